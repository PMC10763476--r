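ih_header_lines <- function(seed = NULL, config_hash = NULL) {
  l <- sprintf("# imputehazard %s", as.character(utils::packageVersion("imputehazard")))
  if (!is.null(seed)) l <- c(l, sprintf("# seed=%s", seed))
  if (!is.null(config_hash)) l <- c(l, sprintf("# config_hash=%s", config_hash))
  l
}

#' Write a cohort as VCF 4.2 plus a sample-group sidecar
#'
#' Genotypes are written unphased (`/` separator), missing as `./.`. The risk
#' designation travels in the INFO field (`RISKALLELE`, `ASSOC`) and the
#' case/control split in a two-column sidecar file, since VCF has no standard
#' phenotype field.
#'
#' @param study a [cohort_study()].
#' @param path output VCF path.
#' @param groups_path sidecar path (default `<path>.groups.tsv`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(study, path, groups_path = paste0(path, ".groups.tsv")) {
  stopifnot(inherits(study, "CohortStudy"))
  genos <- rbind(study$cases, study$controls)
  samples <- rownames(genos)
  s <- study$sites
  gt <- matrix("./.", nrow(s), length(samples))
  for (v in 0:2) gt[t(genos) == v] <- c("0/0", "0/1", "1/1")[v + 1]
  info <- ifelse(s$is_associated,
                 paste0("RISKALLELE=", s$risk_allele, ";ASSOC"), ".")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=imputehazard_%s", utils::packageVersion("imputehazard")),
    paste0("##INFO=<ID=RISKALLELE,Number=1,Type=String,",
           "Description=\"Designated risk allele (ref or alt)\">"),
    "##INFO=<ID=ASSOC,Number=0,Type=Flag,Description=\"Disease-associated site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(s$chrom, s$pos_bp, s$id, s$ref_allele, s$alt_allele, ".",
                "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  write_sample_groups(study, groups_path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
write_sample_groups <- function(study, path) {
  df <- data.frame(
    sample = c(rownames(study$cases), rownames(study$controls)),
    group = rep(c("case", "control"), c(nrow(study$cases), nrow(study$controls))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from VCF
#'
#' Accepts biallelic SNPs with a GT field for every sample; `./.` becomes
#' missing. Multiallelic records and indels are rejected naming the record.
#' The case/control split is taken from the two-column sidecar written by
#' [write_sample_groups()].
#'
#' @param path VCF path.
#' @param groups_path sidecar path (default `<path>.groups.tsv`).
#' @return a [cohort_study()].
#' @export
read_vcf <- function(path, groups_path = paste0(path, ".groups.tsv")) {
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) stop("parse error: VCF lacks a GT FORMAT field")
  alt_list <- VariantAnnotation::alt(vcf)
  ids <- rownames(vcf)
  nalt <- S4Vectors::elementNROWS(alt_list)
  if (any(nalt != 1))
    stop("multiallelic record rejected: ", paste(ids[nalt != 1], collapse = ", "))
  ref_a <- as.character(VariantAnnotation::ref(vcf))
  alt_a <- as.character(unlist(alt_list))
  not_snp <- nchar(ref_a) != 1 | nchar(alt_a) != 1
  if (any(not_snp))
    stop("non-SNP record rejected: ", paste(ids[not_snp], collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- BiocGenerics::start(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  inf <- VariantAnnotation::info(vcf)
  risk <- if ("RISKALLELE" %in% names(inf)) as.character(inf$RISKALLELE) else
    rep(NA_character_, length(ids))
  assoc <- if ("ASSOC" %in% names(inf)) as.logical(inf$ASSOC) else
    rep(FALSE, length(ids))
  risk[is.na(risk) | !assoc] <- "none"

  gt <- g$GT
  parse_gt <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(v) {
      if (any(v == ".") || length(v) != 2) return(NA_integer_)
      sum(as.integer(v))
    }, integer(1))
  }
  genos <- t(apply(gt, 2, parse_gt))  # one row per sample after transpose
  if (is.null(dim(genos))) genos <- matrix(genos, nrow = ncol(gt))
  rownames(genos) <- colnames(gt); colnames(genos) <- ids

  ord <- order(chrom, pos)
  sites <- site_info(id = ids[ord], chrom = chrom[ord], pos_bp = pos[ord],
                     ref_allele = ref_a[ord], alt_allele = alt_a[ord],
                     risk_allele = risk[ord], is_associated = assoc[ord])
  genos <- genos[, ord, drop = FALSE]

  grp <- utils::read.table(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(grp)))
    stop("parse error: sample-group sidecar needs columns 'sample' and 'group'")
  grp <- grp[match(rownames(genos), grp$sample), ]
  if (anyNA(grp$group)) stop("parse error: samples missing from the group sidecar")
  cohort_study(cases = genos[grp$group == "case", , drop = FALSE],
               controls = genos[grp$group == "control", , drop = FALSE],
               sites = sites)
}

#' Read and write hap/legend reference panels
#'
#' The legend holds one row per site (`id pos allele0 allele1`); the hap file
#' holds one row per site of space-separated 0/1 tokens, one column per
#' haplotype.
#'
#' @param hap_path,legend_path file paths.
#' @param panel a [haplotype_panel()] (writer only).
#' @return the reader returns a [haplotype_panel()]; the writer returns
#'   `hap_path` invisibly.
#' @export
read_reference_panel <- function(hap_path, legend_path) {
  leg <- utils::read.table(legend_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "pos", "allele0", "allele1") %in% names(leg)))
    stop("parse error: legend needs columns id, pos, allele0, allele1")
  hap_lines <- readLines(hap_path)
  hap_lines <- hap_lines[nzchar(hap_lines)]
  if (length(hap_lines) != nrow(leg))
    stop("structural error: hap row count (", length(hap_lines),
         ") does not match legend row count (", nrow(leg), ")")
  toks <- strsplit(hap_lines, "[ \t]+")
  H <- length(toks[[1]])
  if (any(lengths(toks) != H))
    stop("structural error: ragged hap rows")
  flat <- unlist(toks)
  if (!all(flat %in% c("0", "1")))
    stop("parse error: non-binary token in hap file: ",
         paste(utils::head(setdiff(unique(flat), c("0", "1"))), collapse = ", "))
  alleles <- t(matrix(as.integer(flat), nrow = H))  # sites x haps -> transpose later
  sites <- site_info(id = leg$id, chrom = if ("chrom" %in% names(leg)) leg$chrom else "1",
                     pos_bp = leg$pos, ref_allele = leg$allele0,
                     alt_allele = leg$allele1)
  haplotype_panel(t(alleles), sites)
}

#' @rdname read_reference_panel
#' @export
write_reference_panel <- function(panel, hap_path, legend_path) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  s <- panel$sites
  leg <- data.frame(id = s$id, pos = s$pos_bp, allele0 = s$ref_allele,
                    allele1 = s$alt_allele, chrom = s$chrom,
                    stringsAsFactors = FALSE)
  utils::write.table(leg, legend_path, sep = " ", quote = FALSE, row.names = FALSE)
  writeLines(apply(t(panel$alleles), 1, paste, collapse = " "), hap_path)
  invisible(hap_path)
}

report_columns <- c(
  "site_id", "region", "experiment", "observed_chi2", "imputed_chi2",
  "info", "maf_study", "maf_reference", "obs_case_risk_freq",
  "imp_case_risk_freq", "n_concordant", "n_discordant", "n_missing",
  "risk_copies_lost_discordant", "risk_copies_gained_discordant",
  "risk_copies_in_missing", "alt_copies_in_missing",
  "monomorphic", "false_negative"
)

#' Write a per-site imputation report as TSV
#'
#' One row per masked site, stable column order. Sites imputed as monomorphic
#' render the imputed chi-square cell as `-`.
#'
#' @param table a report `data.frame` as produced by [run_experiment()].
#' @param path output path.
#' @param header_lines optional comment lines (each prefixed `#`) written
#'   before the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, header_lines = ih_header_lines()) {
  if (is.null(table) || nrow(table) == 0)
    stop("refusing to write an empty report table")
  tab <- table
  for (col in setdiff(report_columns, names(tab))) tab[[col]] <- NA
  tab <- tab[, report_columns]
  num <- vapply(tab, is.numeric, logical(1))
  for (col in names(tab)[num]) tab[[col]] <- formatC(tab[[col]], digits = 6,
                                                     format = "fg", flag = "#")
  tab$imputed_chi2[table$monomorphic %in% TRUE] <- "-"
  tab$imputed_chi2[tab$imputed_chi2 %in% c("NA", NA)] <- "-"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           na.strings = c("NA"), stringsAsFactors = FALSE)
  tab$monomorphic <- as.logical(tab$monomorphic)
  tab$false_negative <- as.logical(tab$false_negative)
  tab$imputed_chi2[tab$imputed_chi2 %in% "-"] <- NA
  tab$imputed_chi2 <- as.numeric(tab$imputed_chi2)
  for (col in intersect(names(tab), setdiff(report_columns,
      c("site_id", "region", "experiment", "monomorphic", "false_negative",
        "imputed_chi2"))))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' Read and write run configuration as YAML
#'
#' @param config a list as built by [run_config()].
#' @param path file path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[setdiff(names(config), "regions")], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
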