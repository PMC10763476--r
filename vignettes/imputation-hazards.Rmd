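---
title: "Why imputation fails at disease loci: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why imputation fails at disease loci: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genotype imputation infers untyped genotypes in a study cohort by modelling
each study haplotype as a mosaic of haplotypes from a large phased reference
panel. At a *disease-associated* locus this procedure has a built-in
conflict: ascertained cases are enriched for risk-bearing haplotypes, so the
haplotype frequencies the copying model borrows from the reference panel are
exactly the frequencies that differ between the panel and the people being
imputed. `imputehazard` packages a controlled re-enactment of that hazard:
simulate a case–control cohort and a reference panel with a known frequency
gap, mask the disease-associated SNPs, impute them back, and account —
allele by allele — for what was lost.

# The copying model

Imputation uses the haploid Li–Stephens hidden Markov model. A target
haplotype is copied from one of $K$ reference haplotypes; the copied source
switches along the chromosome and the copy is read with error. Between
adjacent sites at distance $d$ kb, with recombination intensity $\rho$ per
kb, the switch mass is

$$t = 1 - e^{-\rho d / K}, \qquad
P(\text{stay}) = e^{-\rho d / K} + t/K, \qquad
P(\text{jump to a given other state}) = t/K .$$

Emissions are $1-\varepsilon$ on an allele match and $\varepsilon$ on a
mismatch; a masked or missing site emits nothing and is bridged by the
transition model. Posterior state probabilities come from a forward–backward
pass with per-site rescaling (exact posteriors; likelihoods are not
retained). The alt-allele posterior at a masked site is the
emission-weighted allele of the copied haplotypes,
$\sum_k \gamma_k [(1-\varepsilon)\,a_k + \varepsilon\,(1-a_k)]$, and the
genotype triple $(p_0, p_1, p_2)$ is the convolution of the two
independently imputed haplotypes of an individual. The recursion is
implemented in C++ (the acceptance sweep runs roughly half a million
haploid passes against a 1000-haplotype panel); a brute-force
path-enumeration oracle in the test suite pins the posteriors to $10^{-9}$.

Parameters and defaults:

* `rho_per_kb = 0.4` — no recombination map is used; physical distance times
  a constant suffices for regions below ~40 kb. With $K = 1000$ the
  expected number of switches across 40 kb is of order $10^{-2}$ per
  target, i.e. copying is locally coherent, which is what makes a decoy
  background dangerous.
* `epsilon` — defaults to the population-genetic scaling
  $\tilde\theta / (2(K + \tilde\theta))$ with
  $\tilde\theta = 1/\sum_{i=1}^{K-1} i^{-1}$; about $7\times10^{-5}$ at
  $K = 1000$. One scaffold mismatch therefore effectively disqualifies a
  reference haplotype, so posterior mass at a masked site distributes over
  the *exact* scaffold matches in proportion to their panel frequencies.
* `call_threshold = 0.9` — a genotype is called only if its posterior
  reaches 0.9, otherwise the entry is missing; a tie at the maximum is
  missing (at threshold 0 the argmax is always called). Calling is monotone:
  lowering the threshold never creates missingness.
* info score — per site, with $e_i = p_1 + 2p_2$ and $f_i = p_1 + 4p_2$ and
  $\theta = \sum e_i / 2N$:
  $\mathrm{info} = 1 - \sum_i (f_i - e_i^2) / (2N\theta(1-\theta))$, set to
  1 at $\theta \in \{0, 1\}$. This is the usual ratio-of-information
  measure: 1 means degenerate (certain) posteriors. Note that it measures
  *certainty*, not correctness — confidently wrong calls score high, which
  is one of the study's punchlines.

# What the generator emulates

A region is defined by a handful of founder haplotypes plus group-specific
founder frequencies. Each sampled haplotype picks a founder (cases,
controls and the reference panel each have their own frequency vector), may
recombine once with a second founder (`recombination_rate`, default 0.02),
and is then subjected to independent per-site flips (`mutation_rate`,
default 0.002). Individuals are two independent draws from their group
(Hardy–Weinberg pairing), summed into unphased genotypes; the truth
haplotypes are retained for evaluation.

The load-bearing structural choice is **background sharing**: a risk
founder carries the alt allele at every associated site but copies the
*background* (all non-associated sites) of a designated non-risk founder.
Mask the associated sites and the scaffold can no longer separate the risk
haplotype from its decoy; the copying model falls back on their relative
reference-panel frequencies. With the default preset (risk haplotype at
0.10 in the panel versus a 0.30 decoy) a risk-carrier's alt posterior at a
masked site is about $0.10/0.40 = 0.25$: too low to call the risk allele,
too high to call its absence at threshold 0.9 — so risk carriers go
*missing*, called genotypes become monomorphic for the non-risk allele, and
dosages shrink toward the panel. Setting
`build_founders(background_sharing = FALSE)` produces the benign
configuration (a distinctive risk background), under which masked
associated sites impute essentially perfectly — used by the self-reference
identity tests.

The paper-mirroring preset (`preset_paper()`) fixes the stated world:

* three regions of 118 / 59 / 20 sites over 39.4 / 40.9 / 8.3 kb with
  7 / 8 / 8 associated sites; 92 cases and 93 controls; a reference panel
  of 1000 haplotypes; six founders per region.
* risk-haplotype frequency 0.25 in cases, 0.15 in controls, 0.10 in the
  reference panel. The case and reference values are the emulated study's
  own example (0.27 and 0.098 for its strongest locus, rounded as the spec
  presets them); the control value is chosen so that a single-site allelic
  test at these sample sizes is significant in expectation but not
  overwhelming (expected $\chi^2 \approx 6$), matching the per-SNP
  statistics of the emulated study (4–10). Non-risk founder mass is scaled
  proportionally from the reference vector within each group.
* the first region is polyphyletic (two risk founders carrying differing
  risk-allele subsets on two different shared backgrounds) and its risk
  founders each carry two private non-associated "tag" variants. This
  mirrors a complex, recombination-shaped locus: a dense scaffold retains
  the tags and can rescue the region, an array-density scaffold usually
  drops them. The two monophyletic regions carry no tags — their risk
  alleles co-segregate on a pure decoy background — which is why they fail
  even at full scaffold density.

What the generator does **not** emulate: coalescent genealogies and
realistic allele-frequency spectra, linkage-disequilibrium decay within a
background (founder backgrounds are exchangeable-site Bernoulli draws),
genotyping error in the observed data, and phasing error in the reference
panel. A green test therefore establishes that the *mechanism* — reference
frequency differences plus background confusability produce allele-biased
missingness, monomorphic call sets and false negatives — is faithfully
reproduced and quantified; it does not establish anything about error
*rates* in real cohorts.

# Experiment designs

`make_plans()` builds the three masking designs: `simultaneous_high` masks
every associated site and scaffolds with all remaining sites;
`simultaneous_low` thins the scaffold to a target density (default 0.5
sites/kb, an early-array figure) by even positional spacing (seeded random
thinning is available); `leave_one_out` masks one associated site at a
time, leaving the other associated sites in the scaffold — which is
precisely why it flatters imputation: the remaining risk alleles tag the
risk haplotype perfectly. A region whose thinned scaffold would have fewer
than 10 sites is refused with a typed condition and skipped by the
pipeline with a logged reason (the 8.3 kb region at 0.5/kb would keep ~4
sites), reproducing the emulated study's exclusion of its shortest region
from the sparse design.

Phasing (`phase_em`) is a standard haplotype-frequency EM over enumerated
compatible diplotypes with missing genotypes marginalised, uniform
initialisation plus seeded $10^{-6}$ jitter, tolerance $10^{-8}$ on the
log-likelihood (asserted monotone), and the maximum-a-posteriori diplotype
posterior reported per individual; individuals below 0.9 are excluded
(strictly below — 0.90 is kept). Enumeration is exponential, so the
function refuses more than 25 sites and advises windowing. Consequently the
end-to-end pipeline on the wide regions uses the simulation truth
haplotypes as the scaffold (the imputation engine accepts either), keeping
the phasing module for the short-region use it can honestly serve.

# Error accounting

For each masked site, every individual is concordant, discordant or
missing. Allele-level tallies orient on the designated risk allele:
risk copies lost and gained over discordant calls
($\sum \max(0, \pm(\text{obs} - \text{imp}))$), and the observed risk and
non-risk copies of uncalled entries. A site is monomorphic when its called
genotypes (missing excluded) carry a single allele; a site with no calls at
all is reported as such, not as monomorphic. A false negative is a site
whose observed association is significant at $\alpha$ (0.05, per-SNP, no
multiple-testing correction — matching the emulated study's usage) but
whose imputed association is not, or cannot be computed because the calls
are monomorphic or absent. The tallies satisfy a conservation law (lost +
retained + in-missing = observed risk copies), enforced in tests.

One consequence worth stating: because every uncalled heterozygote
contributes one risk *and* one non-risk copy to the missing tally, the risk
share of error-affected copies cannot exceed ~4/7 even when errors hit risk
carriers exclusively; the hazard manifests as *disproportion* (risk copies
affected far beyond their frequency share), not as an absolute
supermajority of affected copies. The acceptance suite states the stricter
claim anyway and documents its failure rather than redefining it.

# Numerical and design notes

* Determinism: every stochastic step derives from an integer seed
  (sub-seeds are small affine offsets); identical seeds give byte-identical
  outputs, and `run_all()` stamps every file with the package version, seed
  and a configuration hash.
* Underflow: forward and backward messages are renormalised per site; the
  posterior contract is exactness, not likelihood tracking.
* QC mirrors the emulated study: pooled minor allele frequency strictly
  above 1% (pooled, since filtering precedes association), and control-only
  Hardy–Weinberg $\chi^2 < 10$ (1-df Pearson against expectations at the
  control allele frequency).
* Odds ratios are $ad/bc$ oriented so that OR $> 1$ means risk enrichment
  in cases, and `NA` whenever a zero cell makes the ratio inestimable; the
  allelic $\chi^2$ uses no continuity correction and no exact-test
  fallback, matching the default allelic test of standard association
  software (small-count tables are therefore approximate).
* Haplotype frequency tables group by exact identity on the chosen site
  subset — no fuzzy merging — and architecture classification
  (monophyletic/polyphyletic) considers the risk haplotypes observed in the
  study, not reference-only rows.
* Strand is never flipped: study/reference allele disagreement is an error
  by design, since silent strand fixing is its own well-known hazard.

# Known limitations

* The EM phasing enumeration limits full-pipeline phasing to short regions;
  wide-region runs rely on simulation truth haplotypes.
* The diploid copying model is not implemented (pre-phase-then-haploid
  only), so phasing uncertainty does not propagate into imputation.
* Real-data ingestion (VCF plus a sample-group sidecar, hap/legend
  reference panels) is supported and round-trip tested, but no external
  reference panel is bundled and no strand/allele harmonisation is
  attempted.
* Info scores are computed from the package's own posteriors; numerical
  agreement with any external tool's info values is not a goal.
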