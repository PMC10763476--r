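#' @useDynLib imputehazard, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq rbinom runif var
#' @importFrom utils read.table write.table packageVersion
NULL

#' Site metadata table
#'
#' Builds the per-site metadata carried by haplotype panels and cohorts:
#' identifier, chromosome, 1-based physical position, the two alleles, the
#' designated risk allele and whether the site is disease-associated.
#'
#' @param id character site identifiers.
#' @param chrom chromosome labels (recycled).
#' @param pos_bp integer 1-based positions, strictly increasing.
#' @param ref_allele,alt_allele single-character alleles.
#' @param risk_allele one of `"ref"`, `"alt"`, `"none"` per site. Must be
#'   `"none"` exactly at non-associated sites.
#' @param is_associated logical flag per site.
#' @return a `data.frame` with one row per site.
#' @export
site_info <- function(id, chrom = "1", pos_bp, ref_allele = "A",
                      alt_allele = "G", risk_allele = "none",
                      is_associated = FALSE) {
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    ref_allele = as.character(ref_allele), alt_allele = as.character(alt_allele),
    risk_allele = as.character(risk_allele), is_associated = as.logical(is_associated),
    stringsAsFactors = FALSE
  )
  validate_site_info(df)
  df
}

validate_site_info <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("id", "chrom", "pos_bp", "ref_allele", "alt_allele",
            "risk_allele", "is_associated")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols))
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  for (chr in unique(sites$chrom)) {
    p <- sites$pos_bp[sites$chrom == chr]
    if (any(diff(p) <= 0)) stop("pos_bp must be strictly increasing within a region")
  }
  if (!all(sites$risk_allele %in% c("ref", "alt", "none")))
    stop("risk_allele must be 'ref', 'alt' or 'none'")
  bad <- xor(sites$risk_allele != "none", sites$is_associated)
  if (any(bad))
    stop("risk_allele must be designated iff the site is associated: ",
         paste(sites$id[bad], collapse = ", "))
  invisible(sites)
}

#' Phased haplotype panel
#'
#' A panel of phased binary haplotypes (rows) over ordered sites (columns),
#' used both for reference panels and for phased study haplotypes.
#'
#' @param alleles integer matrix in \{0,1\}, H haplotypes x L sites, no missing
#'   entries. `1` counts copies of the alt allele.
#' @param sites site metadata as built by [site_info()].
#' @param labels optional per-haplotype group tags (length H).
#' @return an object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(alleles, sites, labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  validate_site_info(sites)
  if (ncol(alleles) != nrow(sites))
    stop("column count of alleles must equal number of sites")
  if (anyNA(alleles)) stop("haplotype panel must not contain missing entries")
  if (!all(alleles %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  if (!is.null(labels) && length(labels) != nrow(alleles))
    stop("labels must have one entry per haplotype")
  structure(list(alleles = alleles, sites = sites, labels = labels),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d sites (%d associated)\n",
              nrow(x$alleles), ncol(x$alleles), sum(x$sites$is_associated)))
  invisible(x)
}

#' @export
dim.HaplotypePanel <- function(x) dim(x$alleles)

#' Case-control cohort of unphased genotypes
#'
#' @param cases,controls integer genotype matrices over \{0,1,2,NA\}; rows are
#'   individuals, columns are sites; values count alt-allele copies.
#' @param sites shared site metadata ([site_info()]).
#' @param truth optional list with elements `cases` and `controls`, each a list
#'   of two H x L matrices `hap1`, `hap2` holding the simulated truth
#'   haplotypes of every individual (simulation only).
#' @return an object of class `CohortStudy`.
#' @export
cohort_study <- function(cases, controls, sites, truth = NULL) {
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  storage.mode(cases) <- "integer"; storage.mode(controls) <- "integer"
  validate_site_info(sites)
  if (ncol(cases) != nrow(sites) || ncol(controls) != nrow(sites))
    stop("cases and controls must share the cohort site list")
  ok <- function(g) all(g[!is.na(g)] %in% 0:2)
  if (!ok(cases) || !ok(controls)) stop("genotypes must be 0, 1, 2 or NA")
  if (is.null(rownames(cases))) rownames(cases) <- sprintf("case%03d", seq_len(nrow(cases)))
  if (is.null(rownames(controls))) rownames(controls) <- sprintf("ctrl%03d", seq_len(nrow(controls)))
  colnames(cases) <- colnames(controls) <- sites$id
  if (!is.null(truth)) {
    stopifnot(all(c("cases", "controls") %in% names(truth)))
    for (g in c("cases", "controls"))
      for (h in c("hap1", "hap2"))
        stopifnot(identical(dim(truth[[g]][[h]]),
                            dim(if (g == "cases") cases else controls)))
  }
  structure(list(cases = cases, controls = controls, sites = sites, truth = truth),
            class = "CohortStudy")
}

#' @export
print.CohortStudy <- function(x, ...) {
  cat(sprintf("CohortStudy: %d cases, %d controls, %d sites (%d associated)%s\n",
              nrow(x$cases), nrow(x$controls), nrow(x$sites),
              sum(x$sites$is_associated),
              if (is.null(x$truth)) "" else ", truth haplotypes attached"))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the founder panel, the group-specific founder frequency vectors and
#' the noise rates that define one simulated region.
#'
#' @param founders a [haplotype_panel()] of founder haplotypes.
#' @param founder_freqs_reference,founder_freqs_cases,founder_freqs_controls
#'   probability vectors over founders; each must sum to 1 within 1e-12.
#' @param n_reference_haps,n_cases,n_controls sample sizes.
#' @param mutation_rate per-site allele flip probability in sampled haplotypes.
#' @param recombination_rate probability that a sampled haplotype is a single
#'   crossover between two founders.
#' @param seed integer seed; all sampling is deterministic given it.
#' @return an object of class `SimulationConfig`.
#' @export
simulation_config <- function(founders, founder_freqs_reference,
                              founder_freqs_cases, founder_freqs_controls,
                              n_reference_haps, n_cases, n_controls,
                              mutation_rate = 0.002, recombination_rate = 0.02,
                              seed = 1L) {
  stopifnot(inherits(founders, "HaplotypePanel"))
  nf <- nrow(founders$alleles)
  for (nm in c("founder_freqs_reference", "founder_freqs_cases",
               "founder_freqs_controls")) {
    f <- get(nm)
    if (length(f) != nf)
      stop("invalid configuration: ", nm, " must match the founder count")
    if (any(f < 0) || abs(sum(f) - 1) > 1e-12)
      stop("invalid configuration: ", nm, " must be a probability vector summing to 1")
  }
  for (nm in c("mutation_rate", "recombination_rate")) {
    r <- get(nm)
    if (r < 0 || r > 1) stop("invalid configuration: ", nm, " must lie in [0,1]")
  }
  structure(list(
    founders = founders,
    founder_freqs_reference = founder_freqs_reference,
    founder_freqs_cases = founder_freqs_cases,
    founder_freqs_controls = founder_freqs_controls,
    n_reference_haps = as.integer(n_reference_haps),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    mutation_rate = mutation_rate, recombination_rate = recombination_rate,
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Genotype risk-allele dosage given the per-site risk designation.
risk_dosage <- function(genos, risk_allele) {
  if (length(risk_allele) == 1) risk_allele <- rep(risk_allele, ncol(genos))
  out <- genos
  flip <- risk_allele == "ref"
  if (any(flip)) out[, flip] <- 2L - genos[, flip, drop = FALSE]
  out
}
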