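Package: imputehazard
Title: Reference-Panel Bias Hazards of Genotype Imputation at Disease Loci
Version: 0.1.0
Authors@R: person("Winston", "Devlin", email = "wdevlin@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how genotype imputation against a phased
    reference haplotype panel misbehaves at disease-associated loci where
    haplotype frequencies differ between cases and the reference panel.
    Provides a seeded case-control haplotype simulator with founder
    architectures, a Li-Stephens haplotype-copying hidden Markov model for
    imputation with genotype calling and per-site info scores, EM-based
    haplotype phasing for short regions, the study quality-control filters
    and allelic association statistics, masking experiment designs
    (simultaneous low/high density and leave-one-out), and haplotype
    frequency comparisons between cases, controls and the reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    Rcpp,
    S4Vectors,
    digest,
    jsonlite,
    stats,
    utils,
    yaml,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
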