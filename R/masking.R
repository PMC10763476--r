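#' Build masking plans for the three experiment designs
#'
#' `simultaneous_high` masks every associated site at once and scaffolds with
#' all remaining sites. `simultaneous_low` also masks all associated sites but
#' thins the scaffold to approximately `density_target` sites per kb by even
#' positional spacing (array-like tagging); seeded random thinning is
#' available as an option. `leave_one_out` produces one plan per associated
#' site, scaffolding with every other site including the remaining associated
#' ones.
#'
#' @param study a [cohort_study()] with at least one associated site.
#' @param experiment one of `"simultaneous_high"`, `"simultaneous_low"`,
#'   `"leave_one_out"`.
#' @param density_target scaffold density in sites per kb
#'   (`simultaneous_low` only).
#' @param min_scaffold regions whose thinned scaffold would fall below this
#'   many sites are refused with a condition of class `density_unreachable`
#'   (the pipeline logs these as skipped; default 10).
#' @param method thinning method, `"even"` (default) or `"random"`.
#' @param seed seed for random thinning.
#' @return a list of `MaskingPlan` objects, each with `experiment`,
#'   `masked_site_ids`, `scaffold_site_ids` and (low density only)
#'   `target_scaffold_density_per_kb`.
#' @export
make_plans <- function(study,
                       experiment = c("simultaneous_high", "simultaneous_low",
                                      "leave_one_out"),
                       density_target = NULL, min_scaffold = 10L,
                       method = c("even", "random"), seed = 1L) {
  experiment <- match.arg(experiment)
  method <- match.arg(method)
  stopifnot(inherits(study, "CohortStudy"))
  s <- study$sites
  assoc <- s$id[s$is_associated]
  if (length(assoc) == 0) stop("study has no associated site to mask")
  other <- s$id[!s$is_associated]
  new_plan <- function(masked, scaffold, density = NULL) {
    stopifnot(length(intersect(masked, scaffold)) == 0,
              all(c(masked, scaffold) %in% s$id))
    structure(list(experiment = experiment, masked_site_ids = masked,
                   scaffold_site_ids = scaffold,
                   target_scaffold_density_per_kb = density),
              class = "MaskingPlan")
  }
  if (experiment == "simultaneous_high") {
    return(list(new_plan(assoc, other)))
  }
  if (experiment == "simultaneous_low") {
    if (is.null(density_target)) stop("simultaneous_low needs a density_target")
    kb <- (max(s$pos_bp) - min(s$pos_bp)) / 1000
    target_n <- max(1L, round(density_target * kb))
    if (target_n > length(other))
      stop("density target exceeds the available scaffold density (",
           target_n, " wanted, ", length(other), " available)")
    if (target_n < min_scaffold) {
      cond <- structure(
        class = c("density_unreachable", "error", "condition"),
        list(message = sprintf(
          "region too short for the sparse design: %d scaffold sites at %.2g/kb over %.1f kb (< %d required)",
          target_n, density_target, kb, min_scaffold), call = sys.call(-1)))
      stop(cond)
    }
    pick <- if (method == "even") {
      unique(round(seq(1, length(other), length.out = target_n)))
    } else {
      with_seed(seed, sort(sample.int(length(other), target_n)))
    }
    return(list(new_plan(assoc, other[pick], density_target)))
  }
  # leave_one_out: mask one associated site at a time
  lapply(assoc, function(a) new_plan(a, setdiff(s$id, a)))
}

#' @export
print.MaskingPlan <- function(x, ...) {
  cat(sprintf("MaskingPlan[%s]: %d masked, %d scaffold sites\n",
              x$experiment, length(x$masked_site_ids),
              length(x$scaffold_site_ids)))
  invisible(x)
}

#' Run masking experiments end to end
#'
#' For each plan: restrict the cohort to scaffold + masked sites, take the
#' scaffold haplotypes (cohort truth haplotypes by default, or phased ones),
#' impute the masked sites against the reference panel, call genotypes at the
#' configured threshold, compute info scores, rerun the allelic association
#' on the imputed calls and tally errors against the observed genotypes.
#' Leave-one-out plans are merged into one row per site.
#'
#' @param study a [cohort_study()] (QC-filtered upstream if desired).
#' @param reference a [haplotype_panel()] reference panel.
#' @param plans list of plans from [make_plans()].
#' @param impute_config an [imputation_config()]; built with defaults from
#'   `reference` if omitted.
#' @param alpha significance level for association and false negatives.
#' @param haps optional phased scaffold haplotypes (see [impute_masked()]).
#' @param region label carried into the report.
#' @return list with `report` (one row per masked site; see
#'   [write_report()] for columns), `tallies`, and `summary` (mean
#'   concordance, mean info, monomorphic / false-negative counts,
#'   mean observed and imputed case risk-allele frequencies).
#' @export
run_experiment <- function(study, reference, plans, impute_config = NULL,
                           alpha = 0.05, haps = NULL, region = NA_character_) {
  stopifnot(inherits(study, "CohortStudy"))
  if (is.null(impute_config)) impute_config <- imputation_config(reference)
  ref_af <- colMeans(reference$alleles)
  rows <- list(); tallies <- list()
  for (p in seq_along(plans)) {
    plan <- plans[[p]]
    use <- which(study$sites$id %in% c(plan$masked_site_ids,
                                       plan$scaffold_site_ids))
    sub <- subset_sites(study, use)
    sub_haps <- haps
    if (!is.null(sub_haps))
      for (g in c("cases", "controls"))
        for (h in c("hap1", "hap2"))
          sub_haps[[g]][[h]] <- sub_haps[[g]][[h]][, use, drop = FALSE]
    post <- tryCatch(
      impute_masked(sub, plan$masked_site_ids, impute_config, haps = sub_haps),
      error = function(e) stop("plan ", p, " (", plan$experiment, "): ",
                               conditionMessage(e), call. = FALSE))
    calls <- call_genotypes(post)
    isum <- imputation_summary(post, calls)
    cmp <- compare_observed_imputed(sub, calls, post$masked_ids, alpha = alpha)
    t <- cmp$tallies
    m <- match(t$site_id, study$sites$id)
    ra <- study$sites$risk_allele[m]
    obs_case <- risk_dosage(study$cases[, m, drop = FALSE], ra)
    obs_freq <- colMeans(obs_case, na.rm = TRUE) / 2
    ji <- match(t$site_id, post$masked_ids)
    imp_freq <- vapply(seq_along(ji), function(k) {
      tri <- matrix(post$cases[, ji[k], ], ncol = 3)
      d <- mean(tri[, 2] + 2 * tri[, 3]) / 2      # dosage-based, call-free
      if (ra[k] == "ref") 1 - d else d
    }, numeric(1))
    ref_freq <- vapply(seq_along(ji), function(k) {
      rm_ <- match_reference_sites(study$sites[m[k], , drop = FALSE], reference)
      af <- ref_af[rm_]
      min(af, 1 - af)
    }, numeric(1))
    rows[[p]] <- data.frame(
      site_id = t$site_id, region = region, experiment = plan$experiment,
      observed_chi2 = t$observed_chi2, imputed_chi2 = t$imputed_chi2,
      info = isum$info[match(t$site_id, isum$site_id)],
      maf_study = vapply(seq_along(m), function(k) {
        af <- mean(c(study$cases[, m[k]], study$controls[, m[k]]),
                   na.rm = TRUE) / 2
        min(af, 1 - af)
      }, numeric(1)),
      maf_reference = ref_freq,
      obs_case_risk_freq = obs_freq, imp_case_risk_freq = imp_freq,
      n_concordant = t$n_concordant, n_discordant = t$n_discordant,
      n_missing = t$n_missing,
      risk_copies_lost_discordant = t$risk_copies_lost_discordant,
      risk_copies_gained_discordant = t$risk_copies_gained_discordant,
      risk_copies_in_missing = t$risk_copies_in_missing,
      alt_copies_in_missing = t$alt_copies_in_missing,
      monomorphic = t$monomorphic, false_negative = t$false_negative,
      stringsAsFactors = FALSE
    )
    tallies[[p]] <- t
  }
  report <- do.call(rbind, rows)
  tall <- do.call(rbind, tallies)
  n_ind <- nrow(study$cases) + nrow(study$controls)
  denom <- sum(tall$risk_copies_lost_discordant +
                 tall$risk_copies_gained_discordant +
                 tall$risk_copies_in_missing + tall$alt_copies_in_missing)
  summary <- list(
    experiment = plans[[1]]$experiment, region = region,
    n_masked = nrow(report),
    n_monomorphic = sum(report$monomorphic),
    n_false_negative = sum(report$false_negative),
    mean_info = mean(report$info, na.rm = TRUE),
    mean_concordance = mean(report$n_concordant / n_ind),
    mean_obs_case_risk_freq = mean(report$obs_case_risk_freq),
    mean_imp_case_risk_freq = mean(report$imp_case_risk_freq),
    risk_error_share = if (denom == 0) NA_real_ else
      sum(tall$risk_copies_lost_discordant + tall$risk_copies_in_missing) / denom
  )
  list(report = report, tallies = tall, summary = summary)
}
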