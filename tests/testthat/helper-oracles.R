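# Independent oracles and tiny fixture builders shared across tests.

# Brute-force Li-Stephens posteriors by enumerating all K^L copying paths.
# ref: L x K matrix of 0/1; obs: length-L alleles with NA; dist_kb: L-1.
enum_copying_posteriors <- function(ref, obs, dist_kb, rho, eps) {
  L <- nrow(ref); K <- ncol(ref)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  emit <- function(l, k) {
    if (is.na(obs[l])) 1 else if (ref[l, k] == obs[l]) 1 - eps else eps
  }
  w <- apply(paths, 1, function(z) {
    p <- (1 / K) * emit(1, z[1])
    for (l in seq_len(L - 1)) {
      nr <- exp(-rho * dist_kb[l] / K)
      t_ <- 1 - nr
      trans <- if (z[l + 1] == z[l]) nr + t_ / K else t_ / K
      p <- p * trans * emit(l + 1, z[l + 1])
    }
    p
  })
  post <- matrix(0, L, K)
  for (l in seq_len(L))
    for (k in seq_len(K))
      post[l, k] <- sum(w[paths[, l] == k])
  sweep(post, 1, rowSums(post), "/")
}

# Minimal haplotype panel over evenly spaced sites.
toy_panel <- function(alleles, spacing_bp = 1000, assoc = integer(0),
                      risk = "alt", chrom = "1") {
  alleles <- as.matrix(alleles)
  L <- ncol(alleles)
  is_assoc <- seq_len(L) %in% assoc
  sites <- site_info(id = sprintf("s%02d", seq_len(L)), chrom = chrom,
                     pos_bp = seq_len(L) * spacing_bp,
                     risk_allele = ifelse(is_assoc, risk, "none"),
                     is_associated = is_assoc)
  haplotype_panel(alleles, sites)
}

# Cohort with given genotype matrices over the same toy sites.
toy_study <- function(cases, controls, spacing_bp = 1000, assoc = integer(0),
                      risk = "alt", truth = NULL) {
  p <- toy_panel(matrix(0L, 1, ncol(as.matrix(cases))), spacing_bp, assoc, risk)
  cohort_study(cases, controls, p$sites, truth = truth)
}

# Small noise-free simulation used by several tests.
toy_sim <- function(n_founders = 4, n_sites = 10, n_assoc = 2, seed = 7,
                    n_ref = 40, n_cases = 30, n_controls = 30,
                    mutation = 0, recomb = 0,
                    freq_ref = NULL, freq_cases = NULL, freq_controls = NULL,
                    architecture = "monophyletic", sharing = TRUE) {
  founders <- build_founders(n_founders, n_sites, n_assoc, architecture,
                             seed = seed, background_sharing = sharing)
  unif <- rep(1 / n_founders, n_founders)
  simulation_config(
    founders,
    founder_freqs_reference = if (is.null(freq_ref)) unif else freq_ref,
    founder_freqs_cases = if (is.null(freq_cases)) unif else freq_cases,
    founder_freqs_controls = if (is.null(freq_controls)) unif else freq_controls,
    n_reference_haps = n_ref, n_cases = n_cases, n_controls = n_controls,
    mutation_rate = mutation, recombination_rate = recomb, seed = seed
  )
}
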