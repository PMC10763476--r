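#' Quality-control configuration
#'
#' @param min_maf retain sites with pooled minor allele frequency strictly
#'   above this (default 0.01, i.e. MAF above 1%).
#' @param hwe_chi2_max retain sites whose Hardy-Weinberg chi-square in the
#'   controls is strictly below this (default 10).
#' @return an object of class `QCConfig`.
#' @export
qc_config <- function(min_maf = 0.01, hwe_chi2_max = 10) {
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)")
  if (hwe_chi2_max <= 0) stop("hwe_chi2_max must be positive")
  structure(list(min_maf = min_maf, hwe_chi2_max = hwe_chi2_max),
            class = "QCConfig")
}

#' Hardy-Weinberg chi-square for one site
#'
#' 1-df Pearson statistic comparing observed genotype counts with the
#' Hardy-Weinberg expectations computed from the sample allele frequency.
#'
#' @param genos genotypes over \{0,1,2,NA\} (alt-allele copies).
#' @return the chi-square statistic, or `NA` if no genotype is observed or
#'   the site is monomorphic in the sample (the statistic is then 0/0; it is
#'   treated as 0 by [qc_filter()]).
#' @export
hwe_chi2 <- function(genos) {
  g <- genos[!is.na(genos)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (2 * obs[1] + obs[2]) / (2 * n)  # ref-allele frequency
  if (p == 0 || p == 1) return(0)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum((obs - e)^2 / e)
}

#' Apply the study QC filters
#'
#' Retains sites with pooled (cases + controls) MAF strictly above
#' `qc$min_maf` and control-group Hardy-Weinberg chi-square strictly below
#' `qc$hwe_chi2_max`. Sites with no observed genotypes are excluded with
#' reason `"no data"`.
#'
#' @param study a [cohort_study()].
#' @param qc a [qc_config()].
#' @return a list with `study` (filtered cohort, truth haplotypes subset
#'   accordingly) and `excluded` (data.frame of site id and reason).
#' @export
qc_filter <- function(study, qc = qc_config()) {
  stopifnot(inherits(study, "CohortStudy"), inherits(qc, "QCConfig"))
  pooled <- rbind(study$cases, study$controls)
  L <- ncol(pooled)
  reasons <- character(L)
  for (l in seq_len(L)) {
    g <- pooled[, l]
    if (all(is.na(g))) { reasons[l] <- "no data"; next }
    af <- mean(g, na.rm = TRUE) / 2
    maf <- min(af, 1 - af)
    r <- character()
    if (!(maf > qc$min_maf)) r <- c(r, "maf")
    hw <- hwe_chi2(study$controls[, l])
    if (!is.na(hw) && hw >= qc$hwe_chi2_max) r <- c(r, "hwe")
    reasons[l] <- paste(r, collapse = ",")
  }
  keep <- reasons == ""
  excluded <- data.frame(site_id = study$sites$id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  list(study = subset_sites(study, which(keep)), excluded = excluded)
}

# Restrict a cohort (and its truth haplotypes) to site indices `idx`.
subset_sites <- function(study, idx) {
  truth <- study$truth
  if (!is.null(truth))
    for (g in c("cases", "controls"))
      for (h in c("hap1", "hap2"))
        truth[[g]][[h]] <- truth[[g]][[h]][, idx, drop = FALSE]
  sites <- study$sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  cohort_study(study$cases[, idx, drop = FALSE],
               study$controls[, idx, drop = FALSE], sites, truth = truth)
}

#' Allelic chi-square association test for one site
#'
#' Pearson chi-square (no continuity correction) on the 2x2 allele-count
#' table, cases/controls x risk/other. Missing genotypes contribute nothing.
#' The odds ratio is oriented so that OR > 1 means the risk allele is enriched
#' in cases, and is `NA` whenever a zero cell makes it inestimable.
#'
#' @param case_genos,control_genos genotype vectors over \{0,1,2,NA\}
#'   (alt-allele copies).
#' @param risk_allele `"alt"` or `"ref"`; which allele to orient as risk.
#' @param site_id optional identifier carried into the result.
#' @return one-row `data.frame`: site id, the four allele counts, `chi2`,
#'   `p_value`, `odds_ratio`, `maf_study`.
#' @export
allelic_chi2 <- function(case_genos, control_genos, risk_allele = "alt",
                         site_id = NA_character_) {
  risk_allele <- match.arg(risk_allele, c("alt", "ref"))
  ca <- case_genos[!is.na(case_genos)]
  co <- control_genos[!is.na(control_genos)]
  if (length(ca) == 0 || length(co) == 0)
    stop("undefined result: a group has zero non-missing genotypes",
         if (!is.na(site_id)) paste0(" at ", site_id) else "")
  dos <- function(g) if (risk_allele == "alt") g else 2 - g
  a <- sum(dos(ca)); b <- 2 * length(ca) - a     # cases: risk / other
  c_ <- sum(dos(co)); d <- 2 * length(co) - c_   # controls: risk / other
  n <- a + b + c_ + d
  chi2 <- if ((a + c_) == 0 || (b + d) == 0) 0 else
    n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  or <- if (min(a, b, c_, d) == 0) NA_real_ else (a * d) / (b * c_)
  af <- (sum(ca) + sum(co)) / (2 * (length(ca) + length(co)))  # pooled alt freq
  data.frame(site_id = site_id, n_case_risk = a, n_case_other = b,
             n_control_risk = c_, n_control_other = d,
             chi2 = chi2, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
             odds_ratio = or, maf_study = min(af, 1 - af),
             stringsAsFactors = FALSE)
}

#' Allelic association scan over all cohort sites
#'
#' @param study a [cohort_study()].
#' @param alpha significance level recorded in the `significant` column.
#' @return a `data.frame`, one row per site; sites designated `risk_allele ==
#'   "none"` are oriented on the alt allele.
#' @export
assoc_scan <- function(study, alpha = 0.05) {
  s <- study$sites
  rows <- lapply(seq_len(nrow(s)), function(l) {
    ra <- if (s$risk_allele[l] == "ref") "ref" else "alt"
    allelic_chi2(study$cases[, l], study$controls[, l], ra, s$id[l])
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}

#' Compare observed and imputed genotypes at masked sites
#'
#' Classifies every individual x masked-site entry as concordant, discordant
#' or missing, tallies risk-allele copies lost and gained among discordant
#' calls and the allele copies left uncalled, flags sites whose called
#' genotypes carry a single allele (monomorphic) and sites whose observed
#' association is significant but lost after imputation (false negative).
#'
#' @param observed a [cohort_study()] holding the observed genotypes.
#' @param imputed_calls list with `cases` and `controls` call matrices over
#'   the masked sites (as from [call_genotypes()]).
#' @param masked_ids ids of the masked sites.
#' @param alpha significance level for the false-negative determination.
#' @return a list with `tallies` (one row per masked site) and `summary`.
#' @export
compare_observed_imputed <- function(observed, imputed_calls, masked_ids,
                                     alpha = 0.05) {
  stopifnot(inherits(observed, "CohortStudy"))
  for (g in c("cases", "controls")) {
    if (!identical(rownames(imputed_calls[[g]]),
                   rownames(observed[[g]])))
      stop("alignment error: individual sets differ for ", g)
  }
  idx <- match(masked_ids, observed$sites$id)
  if (anyNA(idx)) stop("alignment error: masked sites absent from observed cohort")
  s <- observed$sites[idx, , drop = FALSE]
  n_ind <- nrow(observed$cases) + nrow(observed$controls)

  rows <- lapply(seq_along(idx), function(k) {
    l <- idx[k]
    obs <- c(observed$cases[, l], observed$controls[, l])
    imp <- c(imputed_calls$cases[, masked_ids[k]],
             imputed_calls$controls[, masked_ids[k]])
    ra <- if (s$risk_allele[k] == "ref") "ref" else "alt"
    obs_r <- if (ra == "alt") obs else 2L - obs
    imp_r <- if (ra == "alt") imp else 2L - imp
    miss <- is.na(imp)
    conc <- !miss & imp == obs
    disc <- !miss & imp != obs
    lost <- sum(pmax(0L, obs_r[disc] - imp_r[disc]))
    gained <- sum(pmax(0L, imp_r[disc] - obs_r[disc]))
    retained <- sum(pmin(obs_r[!miss], imp_r[!miss]))
    risk_missing <- sum(obs_r[miss])
    alt_missing <- sum(2L - obs_r[miss])
    called <- imp[!miss]
    no_calls <- length(called) == 0
    mono <- !no_calls && (all(called == 0L) || all(called == 2L))
    obs_assoc <- allelic_chi2(observed$cases[, l], observed$controls[, l],
                              ra, s$id[k])
    imp_ok <- !no_calls && !mono &&
      any(!is.na(imputed_calls$cases[, masked_ids[k]])) &&
      any(!is.na(imputed_calls$controls[, masked_ids[k]]))
    imp_assoc <- if (imp_ok)
      allelic_chi2(imputed_calls$cases[, masked_ids[k]],
                   imputed_calls$controls[, masked_ids[k]], ra, s$id[k])
      else NULL
    obs_sig <- obs_assoc$p_value < alpha
    fn <- obs_sig && (is.null(imp_assoc) || imp_assoc$p_value >= alpha)
    data.frame(
      site_id = s$id[k],
      n_concordant = sum(conc), n_discordant = sum(disc), n_missing = sum(miss),
      risk_copies_lost_discordant = lost,
      risk_copies_gained_discordant = gained,
      risk_copies_retained = retained,
      risk_copies_in_missing = risk_missing,
      alt_copies_in_missing = alt_missing,
      total_observed_risk_copies = sum(obs_r),
      monomorphic = mono, no_calls = no_calls,
      observed_chi2 = obs_assoc$chi2, observed_p = obs_assoc$p_value,
      imputed_chi2 = if (is.null(imp_assoc)) NA_real_ else imp_assoc$chi2,
      imputed_p = if (is.null(imp_assoc)) NA_real_ else imp_assoc$p_value,
      false_negative = fn,
      stringsAsFactors = FALSE
    )
  })
  tallies <- do.call(rbind, rows)
  stopifnot(all(tallies$n_concordant + tallies$n_discordant +
                  tallies$n_missing == n_ind))
  denom <- sum(tallies$risk_copies_lost_discordant +
                 tallies$risk_copies_gained_discordant +
                 tallies$risk_copies_in_missing + tallies$alt_copies_in_missing)
  summary <- list(
    n_sites = nrow(tallies),
    n_monomorphic = sum(tallies$monomorphic),
    n_false_negative = sum(tallies$false_negative),
    mean_concordance = mean(tallies$n_concordant / n_ind),
    # share of error-affected allele copies that were risk copies
    risk_error_share = if (denom == 0) NA_real_ else
      sum(tallies$risk_copies_lost_discordant +
            tallies$risk_copies_in_missing) / denom
  )
  list(tallies = tallies, summary = summary)
}

#' Linkage disequilibrium r-squared between two panel sites
#'
#' Squared correlation of the two binary haplotype columns.
#'
#' @param panel a [haplotype_panel()].
#' @param site_a,site_b site ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(panel, site_a, site_b) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  col <- function(s) {
    l <- if (is.character(s)) match(s, panel$sites$id) else s
    if (is.na(l) || l < 1 || l > ncol(panel$alleles)) stop("unknown site: ", s)
    panel$alleles[, l]
  }
  x <- col(site_a); y <- col(site_b)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined LD: monomorphic column")
  stats::cor(x, y)^2
}
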