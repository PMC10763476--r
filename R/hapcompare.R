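#' Haplotype frequency table across cases, controls and reference
#'
#' Groups haplotypes by exact identity over a chosen ordered site subset and
#' tabulates their frequencies in cases, controls, the pooled study and the
#' reference panel. Rows are sorted by decreasing case frequency. A row
#' carries risk if it bears at least one risk allele at an associated site of
#' the subset.
#'
#' @param case_haps,control_haps haplotype matrices (or [haplotype_panel()]s)
#'   over the same full site set as `reference`.
#' @param reference a [haplotype_panel()]; supplies the site metadata.
#' @param site_subset site ids (or indices) to compare on; must be non-empty.
#' @return a `data.frame` of class `HaplotypeFreqTable` with columns
#'   `haplotype`, `carries_risk`, `freq_cases`, `freq_controls`,
#'   `freq_pooled`, `freq_reference` and `enrichment`
#'   (= freq_cases / freq_reference, `NA` when the reference frequency is 0);
#'   the site subset is kept in the `sites` attribute.
#' @export
haplotype_table <- function(case_haps, control_haps, reference, site_subset) {
  stopifnot(inherits(reference, "HaplotypePanel"))
  idx <- if (is.character(site_subset))
    match(site_subset, reference$sites$id) else as.integer(site_subset)
  if (length(idx) == 0 || anyNA(idx)) stop("empty or unknown site subset")
  sub_sites <- reference$sites[idx, , drop = FALSE]
  pat <- function(x) {
    if (inherits(x, "HaplotypePanel")) {
      i <- match(sub_sites$id, x$sites$id)
      if (anyNA(i)) stop("site subset absent from a haplotype panel")
      m <- x$alleles[, i, drop = FALSE]
    } else {
      m <- as.matrix(x)
      if (ncol(m) == ncol(reference$alleles))
        m <- m[, idx, drop = FALSE]
      else if (ncol(m) != length(idx))
        stop("haplotype matrix does not cover the site subset")
    }
    apply(m, 1, paste, collapse = "")
  }
  ca <- pat(case_haps); co <- pat(control_haps)
  re <- pat(reference)
  pats <- unique(c(ca, co, re))
  freq <- function(x) as.vector(table(factor(x, levels = pats))) / length(x)
  risk_needed <- sub_sites$is_associated
  risk_bit <- ifelse(sub_sites$risk_allele == "ref", "0", "1")
  carries <- vapply(pats, function(p) {
    b <- strsplit(p, "")[[1]]
    any(risk_needed & b == risk_bit)
  }, logical(1))
  out <- data.frame(
    haplotype = pats, carries_risk = unname(carries),
    freq_cases = freq(ca), freq_controls = freq(co),
    freq_pooled = as.vector(table(factor(c(ca, co), levels = pats))) /
      (length(ca) + length(co)),
    freq_reference = freq(re), stringsAsFactors = FALSE
  )
  out$enrichment <- ifelse(out$freq_reference > 0,
                           out$freq_cases / out$freq_reference, NA_real_)
  out <- out[order(-out$freq_cases), ]
  rownames(out) <- NULL
  attr(out, "sites") <- sub_sites
  class(out) <- c("HaplotypeFreqTable", class(out))
  out
}

#' Classify the risk-haplotype architecture
#'
#' Monophyletic if every risk-carrying haplotype bears the identical
#' risk-allele subset at the associated sites; polyphyletic otherwise.
#'
#' @param rows a [haplotype_table()] result.
#' @param associated_ids optional associated-site ids; defaults to the
#'   associated sites of the table's subset.
#' @return `"monophyletic"` or `"polyphyletic"`.
#' @export
classify_architecture <- function(rows, associated_ids = NULL) {
  sites <- attr(rows, "sites")
  if (is.null(sites)) stop("rows must come from haplotype_table()")
  aidx <- if (is.null(associated_ids)) which(sites$is_associated) else
    match(associated_ids, sites$id)
  # classify the study's haplotypes: rows present only in the reference panel
  # say nothing about the origin of the study's risk alleles
  observed <- if ("freq_pooled" %in% names(rows)) rows$freq_pooled > 0 else TRUE
  risk_rows <- rows[rows$carries_risk & observed, , drop = FALSE]
  if (nrow(risk_rows) == 0) stop("no risk haplotypes observed")
  risk_bit <- ifelse(sites$risk_allele[aidx] == "ref", "0", "1")
  subsets <- vapply(risk_rows$haplotype, function(p) {
    b <- strsplit(p, "")[[1]][aidx]
    paste(which(b == risk_bit), collapse = ",")
  }, character(1))
  if (length(unique(subsets)) == 1) "monophyletic" else "polyphyletic"
}

#' Write a haplotype frequency table as TSV
#'
#' @param rows a [haplotype_table()] result.
#' @param path output path.
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(rows, path, header_lines = ih_header_lines()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(as.data.frame(rows), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
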