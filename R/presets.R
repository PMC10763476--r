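# Region presets mirroring the three targeted-sequencing loci: geometry
# (site counts, kb lengths, associated counts) and the case/control/reference
# enrichment of the risk haplotype.

# Split founder mass: risk founders receive `risk_total` (60/40 when two),
# non-risk founders keep their reference-panel proportions rescaled.
founder_freqs <- function(n_founders, risk_founders, risk_total,
                          reference_nonrisk) {
  f <- numeric(n_founders)
  w <- if (length(risk_founders) == 2) c(0.6, 0.4) else 1
  f[risk_founders] <- risk_total * w
  nr <- setdiff(seq_len(n_founders), risk_founders)
  f[nr] <- reference_nonrisk[nr] / sum(reference_nonrisk[nr]) * (1 - risk_total)
  f
}

region_config <- function(name, n_sites, region_kb, n_associated, architecture,
                          seed, n_cases = 92L, n_controls = 93L,
                          n_reference_haps = 1000L,
                          risk_freq_cases = 0.25, risk_freq_controls = 0.15,
                          risk_freq_reference = 0.10,
                          background_freq_reference = 0.30,
                          n_founders = 6L,
                          mutation_rate = 0.002, recombination_rate = 0.02) {
  founders <- build_founders(n_founders, n_sites, n_associated, architecture,
                             seed = seed, region_kb = region_kb,
                             chrom = name)
  risk <- attr(founders, "risk_founders")
  # reference: risk founders hold risk_freq_reference, their background
  # donor(s) hold background_freq_reference, the rest share the remainder
  ref <- numeric(n_founders)
  w <- if (length(risk) == 2) c(0.6, 0.4) else 1
  ref[risk] <- risk_freq_reference * w
  donors <- if (length(risk) == 2 && n_founders >= 4) c(3L, 4L) else
    if (n_founders >= 2) 2L else integer()
  donors <- setdiff(donors, risk)
  ref[donors] <- background_freq_reference * w[seq_along(donors)] /
    sum(w[seq_along(donors)])
  rest <- setdiff(seq_len(n_founders), c(risk, donors))
  ref[rest] <- (1 - risk_freq_reference - background_freq_reference) / length(rest)
  ref <- ref / sum(ref)
  cfg <- simulation_config(
    founders = founders,
    founder_freqs_reference = ref,
    founder_freqs_cases = founder_freqs(n_founders, risk, risk_freq_cases, ref),
    founder_freqs_controls = founder_freqs(n_founders, risk, risk_freq_controls, ref),
    n_reference_haps = n_reference_haps,
    n_cases = n_cases, n_controls = n_controls,
    mutation_rate = mutation_rate, recombination_rate = recombination_rate,
    seed = seed
  )
  cfg$name <- name
  cfg$region_kb <- region_kb
  cfg
}

#' Paper-mirroring and null region presets
#'
#' `preset_paper()` returns the three-region study emulation: 118 sites over
#' 39.4 kb with 7 associated sites on a polyphyletic background, 59 sites over
#' 40.9 kb and 20 sites over 8.3 kb each with 8 associated sites on a
#' monophyletic background; 92 cases, 93 controls, a reference panel of 1000
#' haplotypes, and risk-haplotype frequencies of 0.25 in cases, 0.15 in
#' controls and 0.10 in the reference panel. `preset_null()` keeps the
#' geometry but removes the enrichment (all groups draw from the reference
#' frequencies).
#'
#' @param seed integer seed; each region derives its own sub-seed from it.
#' @return a named list of three `SimulationConfig` objects.
#' @export
preset_paper <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    regionA = region_config("regionA", 118L, 39.4, 7L, "polyphyletic",
                            seed = seed * 101L + 1L),
    regionB = region_config("regionB", 59L, 40.9, 8L, "monophyletic",
                            seed = seed * 101L + 2L),
    regionC = region_config("regionC", 20L, 8.3, 8L, "monophyletic",
                            seed = seed * 101L + 3L)
  )
}

#' @rdname preset_paper
#' @export
preset_null <- function(seed = 1L) {
  cfgs <- preset_paper(seed)
  for (nm in names(cfgs)) {
    cfgs[[nm]]$founder_freqs_cases <- cfgs[[nm]]$founder_freqs_reference
    cfgs[[nm]]$founder_freqs_controls <- cfgs[[nm]]$founder_freqs_reference
  }
  cfgs
}
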