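#' Build a founder haplotype panel
#'
#' Constructs a small set of founder haplotypes over one region. Risk alleles
#' (always the alt allele here) are placed on one founder under the
#' `monophyletic` architecture, or split across two founders carrying
#' differing non-empty subsets under `polyphyletic`. Non-risk founders never
#' carry a risk allele.
#'
#' Each risk founder copies the background (non-associated) alleles of a
#' designated non-risk "background" founder when one is available, so that the
#' risk haplotype is distinguishable from its background only at associated
#' sites. This is what makes simultaneous masking hazardous: once the
#' associated sites are removed, the scaffold cannot separate the risk
#' haplotype from its background, and the copying model falls back on their
#' relative frequencies in the reference panel.
#'
#' @param n_founders number of founders (>= 2; polyphyletic needs >= 4 for
#'   background sharing, and >= 2 associated sites).
#' @param n_sites number of biallelic sites.
#' @param n_associated number of disease-associated sites (<= n_sites).
#' @param architecture `"monophyletic"` or `"polyphyletic"`.
#' @param seed integer seed.
#' @param region_kb physical length of the region in kb.
#' @param chrom chromosome label.
#' @param start_bp 1-based position of the region start.
#' @param n_tags polyphyletic only: number of private non-associated variants
#'   placed on each risk founder (default 2). These emulate the sequencing
#'   -density variants that tag a complex risk haplotype: a dense scaffold
#'   keeps them and can separate the risk haplotype from its background, a
#'   sparse array-like scaffold usually drops them. Monophyletic risk
#'   founders carry none, so their background is a perfect decoy once the
#'   associated sites are masked.
#' @param background_sharing when `TRUE` (default) risk founders copy the
#'   background of a non-risk founder, the hazardous configuration; set
#'   `FALSE` to place the risk alleles on a distinctive background, the
#'   benign case in which masked associated sites stay imputable.
#' @return a [haplotype_panel()] with founder labels `F1..Fn` and an attribute
#'   `risk_founders` giving the indices of founders carrying risk alleles.
#' @export
build_founders <- function(n_founders, n_sites, n_associated,
                           architecture = c("monophyletic", "polyphyletic"),
                           seed = 1L, region_kb = n_sites / 3,
                           chrom = "1", start_bp = 100000L, n_tags = 2L,
                           background_sharing = TRUE) {
  architecture <- match.arg(architecture)
  if (n_associated > n_sites)
    stop("invalid configuration: n_associated exceeds n_sites")
  if (n_founders < 2) stop("invalid configuration: need at least 2 founders")
  if (architecture == "polyphyletic" && n_associated < 2)
    stop("invalid configuration: polyphyletic architecture needs >= 2 associated sites")
  with_seed(seed, {
    span <- max(n_sites + 1, round(region_kb * 1000))
    pos <- start_bp + sort(sample.int(span, n_sites))
    assoc <- sort(sample.int(n_sites, n_associated))
    p_bg <- runif(n_sites, 0.1, 0.9)
    alleles <- matrix(rbinom(n_founders * n_sites, 1L, rep(p_bg, each = n_founders)),
                      nrow = n_founders)
    if (architecture == "monophyletic") {
      risk <- 1L
      if (background_sharing) alleles[1, ] <- alleles[2, ]  # shared background
    } else {
      risk <- c(1L, 2L)
      if (background_sharing && n_founders >= 4) {
        alleles[1, ] <- alleles[3, ]        # backgrounds donated by founders 3, 4
        alleles[2, ] <- alleles[4, ]
      }
    }
    alleles[, assoc] <- 0L
    if (architecture == "monophyletic") {
      alleles[1, assoc] <- 1L
    } else {
      alleles[1, assoc] <- 1L               # all risk alleles
      sub <- assoc[seq_len(ceiling(n_associated / 2))]
      alleles[2, sub] <- 1L                 # a differing non-empty subset
      # the complex origin leaves each risk founder a few private
      # non-associated variants that dense scaffolds can tag
      free <- setdiff(seq_len(n_sites), assoc)
      if (length(free) >= 2 * n_tags && n_tags > 0) {
        tags <- sample(free, 2 * n_tags)
        for (r in 1:2) {
          tg <- tags[seq_len(n_tags) + (r - 1) * n_tags]
          alleles[r, tg] <- 1L - alleles[r, tg]
        }
      }
    }
    is_assoc <- seq_len(n_sites) %in% assoc
    sites <- site_info(
      id = sprintf("snp%04d", seq_len(n_sites)), chrom = chrom, pos_bp = pos,
      ref_allele = "A", alt_allele = "G",
      risk_allele = ifelse(is_assoc, "alt", "none"), is_associated = is_assoc
    )
    panel <- haplotype_panel(alleles, sites,
                             labels = sprintf("F%d", seq_len(n_founders)))
    attr(panel, "risk_founders") <- risk
    panel
  })
}

# Draw n haplotypes by founder resampling: pick a founder per haplotype, allow
# at most one crossover with a second founder, then apply per-site flip noise.
sample_haps <- function(founders, freqs, n, mutation_rate, recombination_rate) {
  H <- nrow(founders$alleles); L <- ncol(founders$alleles)
  if (length(freqs) != H)
    stop("invalid configuration: frequency vector does not match founder count")
  idx <- sample.int(H, n, replace = TRUE, prob = freqs)
  out <- founders$alleles[idx, , drop = FALSE]
  if (recombination_rate > 0 && L > 1) {
    rec <- which(runif(n) < recombination_rate)
    for (i in rec) {
      j <- sample.int(H, 1, prob = freqs)
      cut <- sample.int(L - 1, 1)
      out[i, (cut + 1):L] <- founders$alleles[j, (cut + 1):L]
    }
  }
  if (mutation_rate > 0) {
    flips <- matrix(runif(n * L) < mutation_rate, nrow = n)
    out[flips] <- 1L - out[flips]
  }
  list(alleles = out, origin = idx)
}

#' Sample a reference haplotype panel
#'
#' Draws `n_reference_haps` haplotypes from the founder distribution
#' `founder_freqs_reference`, with per-site flip noise and single crossovers.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [haplotype_panel()]; the founder of origin of every haplotype is
#'   kept in the `origin` attribute.
#' @export
sample_reference_panel <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed + 1L, {
    s <- sample_haps(config$founders, config$founder_freqs_reference,
                     config$n_reference_haps,
                     config$mutation_rate, config$recombination_rate)
    panel <- haplotype_panel(s$alleles, config$founders$sites,
                             labels = sprintf("ref%04d", seq_len(nrow(s$alleles))))
    attr(panel, "origin") <- s$origin
    panel
  })
}

#' Sample a case-control cohort
#'
#' Every individual receives two haplotypes drawn independently from the
#' group-specific founder distribution (Hardy-Weinberg pairing within group),
#' summed into unphased genotypes. Truth haplotypes are retained for
#' simulation-only evaluation. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [cohort_study()] with `truth` attached.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$n_cases <= 0 || config$n_controls <= 0)
    stop("invalid configuration: n_cases and n_controls must be positive")
  draw_group <- function(freqs, n, seed_off) {
    with_seed(config$seed + seed_off, {
      h1 <- sample_haps(config$founders, freqs, n,
                        config$mutation_rate, config$recombination_rate)
      h2 <- sample_haps(config$founders, freqs, n,
                        config$mutation_rate, config$recombination_rate)
      list(hap1 = h1$alleles, hap2 = h2$alleles,
           origin = cbind(h1$origin, h2$origin))
    })
  }
  ca <- draw_group(config$founder_freqs_cases, config$n_cases, 2L)
  co <- draw_group(config$founder_freqs_controls, config$n_controls, 3L)
  study <- cohort_study(
    cases = ca$hap1 + ca$hap2, controls = co$hap1 + co$hap2,
    sites = config$founders$sites,
    truth = list(cases = ca[c("hap1", "hap2")], controls = co[c("hap1", "hap2")])
  )
  attr(study, "origin") <- list(cases = ca$origin, controls = co$origin)
  study
}
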