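#' Imputation configuration
#'
#' Parameters of the haplotype-copying model: recombination intensity per kb,
#' emission mismatch (copy error) probability and the genotype-calling
#' threshold, together with the phased reference panel.
#'
#' The default `epsilon` follows the usual population-genetic scaling of the
#' copying model: with K reference haplotypes and Watterson-style
#' theta = 1 / sum_{i=1}^{K-1} 1/i, epsilon = theta / (2 (K + theta)).
#'
#' @param reference a [haplotype_panel()] used as reference.
#' @param rho_per_kb recombination intensity per kb (default 0.4).
#' @param epsilon emission mismatch probability in (0, 0.5); default derived
#'   from the panel size as above.
#' @param call_threshold posterior needed to call a genotype (default 0.9).
#' @return an object of class `ImputationConfig`.
#' @export
imputation_config <- function(reference, rho_per_kb = 0.4, epsilon = NULL,
                              call_threshold = 0.9) {
  stopifnot(inherits(reference, "HaplotypePanel"))
  K <- nrow(reference$alleles)
  if (is.null(epsilon)) {
    epsilon <- if (K >= 2) {
      theta <- 1 / sum(1 / seq_len(K - 1))
      theta / (2 * (K + theta))
    } else 1e-6
  }
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  if (rho_per_kb < 0) stop("rho_per_kb must be non-negative")
  if (call_threshold < 0 || call_threshold > 1)
    stop("call_threshold must lie in [0, 1]")
  structure(list(reference = reference, rho_per_kb = rho_per_kb,
                 epsilon = epsilon, call_threshold = call_threshold),
            class = "ImputationConfig")
}

# Map study sites onto reference panel columns; alleles must match
# byte-for-byte (no silent strand flipping).
match_reference_sites <- function(sites, reference, what = "site") {
  key <- function(s) paste(s$chrom, s$pos_bp, sep = ":")
  idx <- match(key(sites), key(reference$sites))
  missing <- is.na(idx)
  if (any(missing))
    stop("not imputable: ", what, "(s) absent from the reference panel: ",
         paste(sites$id[missing], collapse = ", "))
  rs <- reference$sites[idx, , drop = FALSE]
  bad <- rs$ref_allele != sites$ref_allele | rs$alt_allele != sites$alt_allele
  if (any(bad))
    stop("allele mismatch between study and reference panel at: ",
         paste(sites$id[bad], collapse = ", "),
         " (strand is never flipped silently)")
  idx
}

#' Copying-state posteriors for one target haplotype
#'
#' Runs the Li-Stephens forward-backward recursion of the target against the
#' reference panel and returns, per site, the posterior distribution over
#' which reference haplotype is being copied. Sites with `NA` in the target
#' (masked or missing) emit nothing and are bridged by the transition model.
#'
#' Transitions between adjacent sites at distance d kb with K haplotypes use
#' switch mass `t = 1 - exp(-rho_per_kb * d / K)`: stay probability
#' `exp(-rho_per_kb * d / K) + t/K`, each other state `t/K`. Emissions are
#' `1 - epsilon` on allele match and `epsilon` on mismatch. Messages are
#' rescaled per site, so posteriors are exact but likelihoods are not kept.
#'
#' @param target integer vector of target alleles over the reference sites
#'   (0/1, `NA` for no observation).
#' @param config an [imputation_config()].
#' @return an L x K matrix of state posteriors, rows summing to 1.
#' @export
copying_posteriors <- function(target, config) {
  stopifnot(inherits(config, "ImputationConfig"))
  ref <- config$reference
  L <- ncol(ref$alleles)
  if (length(target) != L)
    stop("target must cover the ", L, " reference sites (use NA at unobserved sites)")
  dist_kb <- diff(ref$sites$pos_bp) / 1000
  .ls_forward_backward(t(ref$alleles), as.integer(target), dist_kb,
                       config$rho_per_kb, config$epsilon)
}

#' Impute masked sites from scaffold haplotypes
#'
#' Each of an individual's two scaffold haplotypes is imputed independently
#' (haploid copying). At a masked site the alt-allele posterior is the
#' emission-weighted allele of the copied reference haplotypes,
#' `sum_k gamma_k * [(1-eps) if ref_k = alt else eps]`, and the genotype
#' probability triple is the convolution of the two independent allele
#' posteriors.
#'
#' @param study a [cohort_study()] restricted to scaffold + masked sites.
#' @param masked_ids ids of the sites to mask and impute.
#' @param config an [imputation_config()].
#' @param haps scaffold haplotypes: a list with `cases` and `controls`, each
#'   a list of matrices `hap1`, `hap2` over the study sites. Defaults to the
#'   cohort truth haplotypes; phased haplotypes from [phase_em()] can be
#'   supplied instead.
#' @return an object of class `PosteriorGenotypes`: arrays
#'   `cases`/`controls` of dim N x M x 3 (P(dosage 0/1/2)), `masked_ids`,
#'   and `not_imputable` (masked ids absent from the reference panel).
#' @export
impute_masked <- function(study, masked_ids, config, haps = NULL) {
  stopifnot(inherits(study, "CohortStudy"), inherits(config, "ImputationConfig"))
  if (is.null(haps)) haps <- study$truth
  if (is.null(haps))
    stop("no scaffold haplotypes: supply `haps` (e.g. from phase_em) or a ",
         "cohort with truth haplotypes")
  sites <- study$sites
  midx <- match(masked_ids, sites$id)
  if (anyNA(midx)) stop("masked site ids absent from the study: ",
                        paste(masked_ids[is.na(midx)], collapse = ", "))
  scaffold <- setdiff(seq_len(nrow(sites)), midx)
  # scaffold sites must be in the reference; masked sites may individually fail
  ref_idx_scaffold <- match_reference_sites(sites[scaffold, , drop = FALSE],
                                            config$reference, "scaffold site")
  key <- function(s) paste(s$chrom, s$pos_bp, sep = ":")
  m_ref <- match(key(sites[midx, , drop = FALSE]), key(config$reference$sites))
  not_imputable <- masked_ids[is.na(m_ref)]
  keep <- !is.na(m_ref)
  midx_ok <- midx[keep]
  if (length(midx_ok)) {
    # allele agreement for the masked sites that are present
    match_reference_sites(sites[midx_ok, , drop = FALSE], config$reference,
                          "masked site")
  }
  grid_study <- sort(c(scaffold, midx_ok))
  grid_ref <- integer(length(grid_study))
  grid_ref[match(scaffold, grid_study)] <- ref_idx_scaffold
  grid_ref[match(midx_ok, grid_study)] <- m_ref[keep]
  ord <- order(config$reference$sites$pos_bp[grid_ref])
  grid_study <- grid_study[ord]; grid_ref <- grid_ref[ord]
  masked_rows <- match(midx_ok, grid_study)

  ref_alleles <- t(config$reference$alleles[, grid_ref, drop = FALSE])  # L x K
  storage.mode(ref_alleles) <- "integer"
  dist_kb <- diff(config$reference$sites$pos_bp[grid_ref]) / 1000
  eps <- config$epsilon; rho <- config$rho_per_kb
  is_masked_row <- seq_along(grid_study) %in% masked_rows

  impute_group <- function(h, ind_names) {
    n <- nrow(h$hap1)
    tgt <- function(hm) {
      m <- hm[, grid_study, drop = FALSE]
      m[, is_masked_row] <- NA_integer_
      storage.mode(m) <- "integer"
      m
    }
    a1 <- .ls_impute_many(ref_alleles, tgt(h$hap1), dist_kb, rho, eps,
                          as.integer(masked_rows))
    a2 <- .ls_impute_many(ref_alleles, tgt(h$hap2), dist_kb, rho, eps,
                          as.integer(masked_rows))
    post <- array(NA_real_, c(n, length(masked_rows), 3))
    post[, , 1] <- (1 - a1) * (1 - a2)
    post[, , 2] <- a1 * (1 - a2) + (1 - a1) * a2
    post[, , 3] <- a1 * a2
    dimnames(post) <- list(ind_names, masked_ids[keep], c("p0", "p1", "p2"))
    post
  }
  structure(list(cases = impute_group(haps$cases, rownames(study$cases)),
                 controls = impute_group(haps$controls, rownames(study$controls)),
                 masked_ids = masked_ids[keep],
                 not_imputable = not_imputable,
                 call_threshold = config$call_threshold),
            class = "PosteriorGenotypes")
}

#' Call genotypes from posterior triples
#'
#' Calls the maximum-probability genotype iff its posterior reaches
#' `call_threshold`; otherwise the genotype is left missing. A tie for the
#' maximum also yields missing (unless the threshold is 0, in which case the
#' argmax is always called).
#'
#' @param post a `PosteriorGenotypes` object (or an N x M x 3 array).
#' @param call_threshold calling threshold; defaults to the one recorded at
#'   imputation time (0.9).
#' @return list with `cases` and `controls` call matrices over \{0,1,2,NA\}.
#' @export
call_genotypes <- function(post, call_threshold = NULL) {
  thr <- if (!is.null(call_threshold)) call_threshold
  else if (!is.null(post$call_threshold)) post$call_threshold else 0.9
  call_arr <- function(a) {
    n <- dim(a)[1]; m <- dim(a)[2]
    out <- matrix(NA_integer_, n, m, dimnames = dimnames(a)[1:2])
    for (j in seq_len(m)) {
      p <- a[, j, , drop = TRUE]
      p <- matrix(p, nrow = n)
      mx <- pmax(p[, 1], p[, 2], p[, 3])
      amax <- max.col(p, ties.method = "first") - 1L
      tie <- (p[, 1] == mx) + (p[, 2] == mx) + (p[, 3] == mx) > 1
      ok <- mx >= thr & (!tie | thr == 0)
      out[ok, j] <- amax[ok]
    }
    out
  }
  if (is.array(post) && length(dim(post)) == 3) return(call_arr(post))
  list(cases = call_arr(post$cases), controls = call_arr(post$controls))
}

#' Per-site imputation info score
#'
#' Ratio-of-information certainty measure on the genotype posteriors: with
#' per-individual expected dosage `e_i = p1 + 2 p2` and second moment
#' `f_i = p1 + 4 p2`, and `theta = sum(e_i) / (2N)`,
#' `info = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`; by convention
#' `info = 1` when `theta` is 0 or 1. A value of 1 means no uncertainty in
#' the imputed genotypes.
#'
#' @param post a `PosteriorGenotypes` object.
#' @param site masked site id or index.
#' @return the info score (<= 1).
#' @export
info_score <- function(post, site) {
  j <- if (is.character(site)) match(site, post$masked_ids) else site
  if (is.na(j)) stop("unknown masked site: ", site)
  tri <- rbind(matrix(post$cases[, j, ], ncol = 3),
               matrix(post$controls[, j, ], ncol = 3))
  e <- tri[, 2] + 2 * tri[, 3]
  f <- tri[, 2] + 4 * tri[, 3]
  n <- nrow(tri)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
}

#' Summarise imputation output per masked site
#'
#' @param post a `PosteriorGenotypes` object.
#' @param calls output of [call_genotypes()]; recomputed if omitted.
#' @return data.frame: site id, info score, imputed MAF over called
#'   genotypes, imputed (dosage-based) alt-allele frequency, called and
#'   missing counts.
#' @export
imputation_summary <- function(post, calls = NULL) {
  if (is.null(calls)) calls <- call_genotypes(post)
  all_calls <- rbind(calls$cases, calls$controls)
  rows <- lapply(seq_along(post$masked_ids), function(j) {
    cc <- all_calls[, j]
    called <- cc[!is.na(cc)]
    tri <- rbind(matrix(post$cases[, j, ], ncol = 3),
                 matrix(post$controls[, j, ], ncol = 3))
    dose <- mean(tri[, 2] + 2 * tri[, 3]) / 2
    af <- if (length(called)) mean(called) / 2 else NA_real_
    data.frame(site_id = post$masked_ids[j], info = info_score(post, j),
               imputed_maf = if (is.na(af)) NA_real_ else min(af, 1 - af),
               imputed_alt_dosage_freq = dose,
               n_called = length(called), n_missing = sum(is.na(cc)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
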