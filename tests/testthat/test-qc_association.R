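test_that("qc_filter applies the MAF and control-HWE rules", {
  # controls exactly at HWE with p = 0.9: (81, 18, 1) ref-hom/het/alt-hom
  hwe_ok <- c(rep(0L, 81), rep(1L, 18), rep(2L, 1))
  expect_equal(hwe_chi2(hwe_ok), 0)
  # (50, 0, 50): p = q = 0.5, expected (25, 50, 25) -> chi2 = 100
  hwe_bad <- c(rep(0L, 50), rep(2L, 50))
  expect_equal(hwe_chi2(hwe_bad), 100)

  n <- 100
  cases <- cbind(hwe_ok[seq_len(n)], rep(0L, n), hwe_ok[seq_len(n)])
  # site 2: pooled MAF 0.005 (2 alt copies in 400); site 3: HWE failure
  controls <- cbind(hwe_ok[seq_len(n)], c(1L, rep(0L, n - 1)), hwe_bad)
  st <- toy_study(cases, controls)
  res <- qc_filter(st, qc_config(min_maf = 0.01, hwe_chi2_max = 10))
  expect_equal(res$study$sites$id, "s01")
  expect_equal(res$excluded$site_id, c("s02", "s03"))
  expect_equal(res$excluded$reason, c("maf", "hwe"))

  # a site with no data at all is excluded with its own reason
  cases[, 2] <- NA; controls[, 2] <- NA
  res2 <- qc_filter(toy_study(cases, controls))
  expect_true("no data" %in% res2$excluded$reason)
})

test_that("allelic_chi2 matches the independent 2x2 Pearson oracle", {
  expand <- function(risk, other) {
    # genotype vector with given allele counts (risk = alt copies)
    n <- (risk + other) / 2
    g <- integer(n)
    g[seq_len(risk %/% 2)] <- 2L
    if (risk %% 2) g[risk %/% 2 + 1] <- 1L
    g
  }
  # the worked example: cases 30/154, controls 14/172 risk/other alleles
  ca <- expand(30, 154); co <- expand(14, 172)
  res <- allelic_chi2(ca, co, "alt", "rsX")
  oracle <- chisq.test(matrix(c(30, 14, 154, 172), 2), correct = FALSE)
  expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-9)
  expect_equal(res$odds_ratio, (30 * 172) / (154 * 14), tolerance = 1e-12)

  # randomised agreement with the oracle, both allele orientations
  set.seed(42)
  for (i in 1:25) {
    ca <- sample(0:2, 40, replace = TRUE)
    co <- sample(0:2, 50, replace = TRUE)
    ra <- sample(c("alt", "ref"), 1)
    res <- allelic_chi2(ca, co, ra)
    m <- matrix(c(res$n_case_risk, res$n_control_risk,
                  res$n_case_other, res$n_control_other), 2)
    if (any(colSums(m) == 0)) next
    oracle <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-9)
  }
})

test_that("allelic_chi2 null identity, zero-cell OR and error cases", {
  g <- c(rep(0L, 5), rep(1L, 4), rep(2L, 1))
  res <- allelic_chi2(g, g)
  expect_equal(res$chi2, 0)
  expect_equal(res$odds_ratio, 1)
  # risk allele absent from controls but present in cases -> OR inestimable
  res2 <- allelic_chi2(c(1L, 1L, 0L), c(0L, 0L, 0L))
  expect_true(is.na(res2$odds_ratio))
  expect_gt(res2$chi2, 0)
  expect_error(allelic_chi2(c(NA_integer_, NA), c(0L, 1L)), "undefined")
})

test_that("swapping groups inverts the odds ratio and preserves chi-square", {
  set.seed(7)
  for (i in 1:10) {
    ca <- sample(0:2, 30, replace = TRUE)
    co <- sample(0:2, 30, replace = TRUE)
    a <- allelic_chi2(ca, co); b <- allelic_chi2(co, ca)
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    if (!is.na(a$odds_ratio))
      expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
  }
})

test_that("compare_observed_imputed reproduces the worked 5-individual case", {
  # observed risk dosages 2,1,1,0,0; imputed 1,missing,1,0,0
  obs_cases <- matrix(c(2L, 1L, 1L), 3, 1)
  obs_controls <- matrix(c(0L, 0L), 2, 1)
  st <- toy_study(obs_cases, obs_controls, assoc = 1, risk = "alt")
  imp <- list(cases = matrix(c(1L, NA, 1L), 3, 1,
                             dimnames = list(rownames(st$cases), "s01")),
              controls = matrix(c(0L, 0L), 2, 1,
                                dimnames = list(rownames(st$controls), "s01")))
  res <- compare_observed_imputed(st, imp, "s01")
  t <- res$tallies
  expect_equal(t$n_concordant, 3)
  expect_equal(t$n_discordant, 1)
  expect_equal(t$n_missing, 1)
  expect_equal(t$risk_copies_lost_discordant, 1)
  expect_equal(t$risk_copies_gained_discordant, 0)
  expect_equal(t$risk_copies_in_missing, 1)
  expect_equal(t$alt_copies_in_missing, 1)
  expect_false(t$monomorphic)
})

test_that("identity imputation is fully concordant; monomorphic flags fire", {
  cfg <- toy_sim(n_assoc = 2, seed = 31)
  st <- sample_cohort(cfg)
  masked <- st$sites$id[st$sites$is_associated]
  ident <- list(cases = st$cases[, masked, drop = FALSE],
                controls = st$controls[, masked, drop = FALSE])
  res <- compare_observed_imputed(st, ident, masked)
  expect_true(all(res$tallies$n_discordant == 0))
  expect_true(all(res$tallies$n_missing == 0))
  expect_true(all(!res$tallies$false_negative))

  # an observed-significant site imputed all homozygous major:
  # monomorphic and a false negative
  ca <- matrix(c(rep(2L, 12), rep(1L, 10), rep(0L, 8)), ncol = 1)
  co <- matrix(c(rep(2L, 2), rep(1L, 8), rep(0L, 20)), ncol = 1)
  st2 <- toy_study(ca, co, assoc = 1)
  expect_lt(allelic_chi2(ca[, 1], co[, 1])$p_value, 0.05)
  zero <- list(cases = matrix(0L, 30, 1, dimnames = list(rownames(st2$cases), "s01")),
               controls = matrix(0L, 30, 1, dimnames = list(rownames(st2$controls), "s01")))
  res2 <- compare_observed_imputed(st2, zero, "s01")
  expect_true(res2$tallies$monomorphic)
  expect_true(res2$tallies$false_negative)
})

test_that("risk-copy tallies are conserved", {
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    obs_c <- matrix(sample(0:2, n, TRUE), ncol = 1)
    obs_k <- matrix(sample(0:2, n, TRUE), ncol = 1)
    st <- toy_study(obs_c, obs_k, assoc = 1,
                    risk = sample(c("alt", "ref"), 1))
    imp_c <- matrix(sample(c(0:2, NA), n, TRUE), ncol = 1,
                    dimnames = list(rownames(st$cases), "s01"))
    imp_k <- matrix(sample(c(0:2, NA), n, TRUE), ncol = 1,
                    dimnames = list(rownames(st$controls), "s01"))
    t <- compare_observed_imputed(st, list(cases = imp_c, controls = imp_k),
                                  "s01")$tallies
    expect_equal(t$risk_copies_lost_discordant + t$risk_copies_retained +
                   t$risk_copies_in_missing, t$total_observed_risk_copies)
  }
})

test_that("ld_r2 matches the direct haplotype-count formula", {
  # AB/Ab/aB/ab counts (2,1,1,2) with A = a l l e l e 1
  haps <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1), c(0, 0), c(0, 0))
  p <- toy_panel(haps)
  pA <- 3 / 6; pB <- 3 / 6; pAB <- 2 / 6
  expect_equal(ld_r2(p, "s01", "s02"),
               (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-12)
  # identical columns -> perfect LD; orthogonal columns -> 0
  p2 <- toy_panel(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(ld_r2(p2, 1, 2), 1)
  expect_equal(ld_r2(p2, 1, 3), 0)
  p3 <- toy_panel(cbind(c(1, 1), c(0, 0)))
  expect_error(ld_r2(p3, 1, 2), "undefined LD")
})

test_that("null simulation keeps the allelic test calibrated", {
  # no enrichment: the rejection rate at alpha = 0.05 stays nominal
  set.seed(123)
  pvals <- c()
  for (r in 1:40) {
    cfg <- toy_sim(n_founders = 16, n_sites = 8, n_assoc = 0, seed = 1000 + r,
                   n_cases = 50, n_controls = 50, mutation = 0.002)
    st <- sample_cohort(cfg)
    sc <- tryCatch(assoc_scan(qc_filter(st)$study), error = function(e) NULL)
    if (!is.null(sc)) pvals <- c(pvals, sc$p_value)
  }
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_gt(length(pvals), 250)
  expect_lt(abs(rate - 0.05), 3 * se + 0.02)  # small-sample slack for LD clustering
})
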