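#' Assemble a run configuration
#'
#' @param preset `"paper"` (three-region study emulation with risk-haplotype
#'   enrichment 0.25 / 0.15 / 0.10 in cases / controls / reference) or
#'   `"null"` (same geometry, no enrichment).
#' @param seed integer master seed; recorded in every output header.
#' @param out_dir output directory.
#' @param experiments subset of the three designs to run.
#' @param density_target scaffold density (sites per kb) for the sparse
#'   design (default 0.5, an early-array density).
#' @param reference_panel `"external"` (simulated reference panel) or
#'   `"self"` (the pooled study's own truth haplotypes as reference).
#' @param alpha significance level.
#' @param qc a [qc_config()], or `NULL` to skip QC.
#' @param rho_per_kb,call_threshold copying-model parameters
#'   (see [imputation_config()]).
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(preset = c("paper", "null"), seed = 1L,
                       out_dir = tempfile("hazard_run_"),
                       experiments = c("simultaneous_low", "simultaneous_high",
                                       "leave_one_out"),
                       density_target = 0.5,
                       reference_panel = c("external", "self"),
                       alpha = 0.05, qc = qc_config(),
                       rho_per_kb = 0.4, call_threshold = 0.9) {
  preset <- match.arg(preset)
  reference_panel <- match.arg(reference_panel)
  experiments <- match.arg(experiments, several.ok = TRUE,
                           choices = c("simultaneous_low", "simultaneous_high",
                                       "leave_one_out"))
  if (!is.null(qc) && !inherits(qc, "QCConfig"))   # e.g. round-tripped YAML
    qc <- qc_config(min_maf = qc$min_maf, hwe_chi2_max = qc$hwe_chi2_max)
  structure(list(preset = preset, seed = as.integer(seed), out_dir = out_dir,
                 experiments = experiments, density_target = density_target,
                 reference_panel = reference_panel, alpha = alpha, qc = qc,
                 rho_per_kb = rho_per_kb, call_threshold = call_threshold),
            class = "RunConfig")
}

log_stage <- function(..., quiet = FALSE) {
  if (!quiet) message(sprintf("[imputehazard] %s", sprintf(...)))
}

#' Run the full pipeline
#'
#' simulate -> QC -> plan -> impute -> call -> evaluate -> haplotype-compare,
#' per region and experiment, writing a per-site report, an error tally, a
#' haplotype frequency table and a run summary under `config$out_dir`. Every
#' output carries a header with the package version, the seed and a hash of
#' the configuration. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage logging.
#' @return invisibly, a list with `manifest` (data.frame of written files),
#'   `summaries` (per region x experiment) and `bias_flags`.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest::digest(config[setdiff(names(config), "out_dir")])
  hdr <- ih_header_lines(seed = config$seed, config_hash = cfg_hash)
  cfgs <- if (config$preset == "paper") preset_paper(config$seed) else
    preset_null(config$seed)
  manifest <- list(); summaries <- list(); bias_flags <- character(0)
  emit <- function(path, writer) {
    writer(path)
    path
  }
  for (nm in names(cfgs)) {
    sim <- cfgs[[nm]]
    t0 <- proc.time()[["elapsed"]]
    reference <- sample_reference_panel(sim)
    study <- sample_cohort(sim)
    log_stage("simulate region=%s sites=%d cases=%d controls=%d ref_haps=%d (%.1fs)",
              nm, nrow(study$sites), nrow(study$cases), nrow(study$controls),
              nrow(reference$alleles), proc.time()[["elapsed"]] - t0,
              quiet = quiet)
    if (!is.null(config$qc)) {
      qcres <- qc_filter(study, config$qc)
      log_stage("qc region=%s retained=%d excluded=%d", nm,
                nrow(qcres$study$sites), nrow(qcres$excluded), quiet = quiet)
      study <- qcres$study
    }
    if (config$reference_panel == "self") {
      pooled <- rbind(study$truth$cases$hap1, study$truth$cases$hap2,
                      study$truth$controls$hap1, study$truth$controls$hap2)
      reference <- haplotype_panel(pooled, study$sites)
      log_stage("reference=self region=%s haps=%d", nm, nrow(pooled),
                quiet = quiet)
    }
    icfg <- imputation_config(reference, rho_per_kb = config$rho_per_kb,
                              call_threshold = config$call_threshold)
    for (exp in config$experiments) {
      t0 <- proc.time()[["elapsed"]]
      plans <- tryCatch(
        make_plans(study, exp, density_target = config$density_target),
        density_unreachable = function(e) {
          log_stage("skip region=%s experiment=%s reason=%s", nm, exp,
                    conditionMessage(e), quiet = quiet)
          NULL
        })
      if (is.null(plans)) next
      res <- run_experiment(study, reference, plans, impute_config = icfg,
                            alpha = config$alpha, region = nm)
      base <- file.path(config$out_dir, paste0(nm, "_", exp))
      f_rep <- emit(paste0(base, "_report.tsv"),
                    function(p) write_report(res$report, p, hdr))
      f_tal <- emit(paste0(base, "_tally.tsv"), function(p) {
        con <- file(p, "w"); on.exit(close(con))
        writeLines(hdr, con)
        utils::write.table(res$tallies, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      manifest[[paste(nm, exp, "report")]] <-
        data.frame(region = nm, experiment = exp, kind = "report",
                   file = f_rep, stringsAsFactors = FALSE)
      manifest[[paste(nm, exp, "tally")]] <-
        data.frame(region = nm, experiment = exp, kind = "tally",
                   file = f_tal, stringsAsFactors = FALSE)
      summaries[[paste(nm, exp)]] <- res$summary
      log_stage(paste0("evaluate region=%s experiment=%s masked=%d ",
                       "monomorphic=%d false_negative=%d concordance=%.3f (%.1fs)"),
                nm, exp, res$summary$n_masked, res$summary$n_monomorphic,
                res$summary$n_false_negative, res$summary$mean_concordance,
                proc.time()[["elapsed"]] - t0, quiet = quiet)
      if (res$summary$n_false_negative > 0 ||
          any(res$report$monomorphic &
              res$report$observed_chi2 > stats::qchisq(1 - config$alpha, 1))) {
        bias_flags <- c(bias_flags, paste(nm, exp))
        log_stage("WARNING bias flag region=%s experiment=%s", nm, exp,
                  quiet = quiet)
      }
    }
    # haplotype comparison over all study sites, from the truth haplotypes
    tab <- haplotype_table(
      rbind(study$truth$cases$hap1, study$truth$cases$hap2),
      rbind(study$truth$controls$hap1, study$truth$controls$hap2),
      if (config$reference_panel == "self") reference else {
        # reference panel restricted to the (QC-filtered) study sites
        ref_idx <- match_reference_sites(study$sites, reference)
        haplotype_panel(reference$alleles[, ref_idx, drop = FALSE], study$sites)
      },
      study$sites$id)
    f_hap <- file.path(config$out_dir, paste0(nm, "_haplotypes.tsv"))
    write_haplotype_table(tab, f_hap, hdr)
    manifest[[paste(nm, "haplotypes")]] <-
      data.frame(region = nm, experiment = "all", kind = "haplotypes",
                 file = f_hap, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  sum_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(region = s$region, experiment = s$experiment,
               n_masked = s$n_masked, n_monomorphic = s$n_monomorphic,
               n_false_negative = s$n_false_negative,
               mean_info = s$mean_info, mean_concordance = s$mean_concordance,
               mean_obs_case_risk_freq = s$mean_obs_case_risk_freq,
               mean_imp_case_risk_freq = s$mean_imp_case_risk_freq,
               risk_error_share = s$risk_error_share,
               stringsAsFactors = FALSE)))
  rownames(sum_df) <- NULL
  f_sum <- file.path(config$out_dir, "summary.tsv")
  con <- file(f_sum, "w"); writeLines(hdr, con)
  utils::write.table(sum_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  f_man <- file.path(config$out_dir, "manifest.tsv")
  con <- file(f_man, "w"); writeLines(hdr, con)
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(manifest = man, summaries = sum_df, bias_flags = bias_flags,
                 out_dir = config$out_dir, config_hash = cfg_hash))
}
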