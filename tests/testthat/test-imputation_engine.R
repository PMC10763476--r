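test_that("forward-backward equals the path-enumeration oracle", {
  set.seed(99)
  for (i in 1:100) {
    K <- sample(2:4, 1); L <- sample(2:5, 1)
    ref <- matrix(rbinom(K * L, 1, 0.5), nrow = K)  # H x L panel
    panel <- toy_panel(ref, spacing_bp = sample(500:5000, 1))
    rho <- runif(1, 0, 2); eps <- runif(1, 0.001, 0.3)
    cfg <- imputation_config(panel, rho_per_kb = rho, epsilon = eps)
    target <- rbinom(L, 1, 0.5)
    target[sample(L, sample(0:(L - 1), 1))] <- NA  # some unobserved sites
    got <- copying_posteriors(target, cfg)
    want <- enum_copying_posteriors(t(ref), target,
                                    diff(panel$sites$pos_bp) / 1000, rho, eps)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("single-state and identical-haplotype limits are exact", {
  panel <- toy_panel(matrix(c(1, 0, 1, 1), 1, 4))
  cfg <- imputation_config(panel, epsilon = 0.01)
  post <- copying_posteriors(c(1, 0, NA, 1), cfg)
  expect_true(all(post == 1))

  # rho = 0, tiny epsilon, target equals reference haplotype 2 exactly
  ref <- rbind(c(0, 0, 1, 0), c(1, 0, 1, 1), c(0, 1, 0, 0))
  cfg2 <- imputation_config(toy_panel(ref), rho_per_kb = 0, epsilon = 1e-9)
  post2 <- copying_posteriors(c(1, 0, 1, 1), cfg2)
  expect_true(all(post2[, 2] > 1 - 1e-6))
})

test_that("impute_masked is forced when the reference is unanimous", {
  ref <- cbind(rep(1, 6), rbinom(6, 1, 0.5), rbinom(6, 1, 0.5))
  panel <- toy_panel(ref)
  truth <- function(n, g) list(hap1 = matrix(rep(g, n), n, 3, byrow = TRUE),
                               hap2 = matrix(rep(g, n), n, 3, byrow = TRUE))
  st <- cohort_study(matrix(2L, 4, 3), matrix(2L, 3, 3), panel$sites,
                     truth = list(cases = truth(4, c(1, 1, 1)),
                                  controls = truth(3, c(1, 1, 1))))
  cfg <- imputation_config(panel, epsilon = 1e-9)
  post <- impute_masked(st, "s01", cfg)
  expect_equal(unname(post$cases[, 1, ]),
               matrix(rep(c(0, 0, 1), each = 4), 4), tolerance = 1e-6)
})

test_that("self-reference identity recovers observed genotypes exactly", {
  cfg <- toy_sim(n_founders = 6, n_sites = 15, n_assoc = 3, seed = 41,
                 n_cases = 25, n_controls = 25, mutation = 0, recomb = 0,
                 sharing = FALSE)
  st <- sample_cohort(cfg)
  own <- haplotype_panel(
    rbind(st$truth$cases$hap1, st$truth$cases$hap2,
          st$truth$controls$hap1, st$truth$controls$hap2), st$sites)
  icfg <- imputation_config(own)
  masked <- st$sites$id[st$sites$is_associated]
  post <- impute_masked(st, masked, icfg)
  calls <- call_genotypes(post)
  expect_identical(unname(calls$cases), unname(st$cases[, masked]))
  expect_identical(unname(calls$controls), unname(st$controls[, masked]))
})

test_that("an uncorrelated masked site is imputed at the reference frequency", {
  # reference: masked site independent of the scaffold, alt frequency f
  set.seed(5)
  K <- 400; f <- 0.3
  scaffold <- matrix(rbinom(K * 4, 1, 0.5), K, 4)
  masked_col <- rbinom(K, 1, f)
  panel <- toy_panel(cbind(scaffold[, 1:2], masked_col, scaffold[, 3:4]))
  st <- cohort_study(matrix(0L, 2, 5), matrix(0L, 2, 5), panel$sites,
                     truth = list(
                       cases = list(hap1 = matrix(rbinom(10, 1, 0.5), 2, 5),
                                    hap2 = matrix(rbinom(10, 1, 0.5), 2, 5)),
                       controls = list(hap1 = matrix(rbinom(10, 1, 0.5), 2, 5),
                                       hap2 = matrix(rbinom(10, 1, 0.5), 2, 5))))
  post <- impute_masked(st, "s03", imputation_config(panel))
  dose <- post$cases[, 1, 2] + 2 * post$cases[, 1, 3]
  expect_lt(max(abs(dose - 2 * f)), 0.15)
})

test_that("reference coverage rules: scaffold gaps fatal, masked gaps reported", {
  set.seed(8)
  full <- toy_panel(matrix(rbinom(6 * 5, 1, 0.5), 6, 5))
  truth <- list(hap1 = matrix(rbinom(10, 1, 0.5), 2, 5),
                hap2 = matrix(rbinom(10, 1, 0.5), 2, 5))
  st <- cohort_study(truth$hap1 + truth$hap2, truth$hap1 + truth$hap2,
                     full$sites, truth = list(cases = truth, controls = truth))
  # reference lacking site s03
  gap <- haplotype_panel(full$alleles[, -3], full$sites[-3, ])
  icfg <- imputation_config(gap)
  # s03 masked: reported not-imputable, s02 proceeds
  post <- impute_masked(st, c("s02", "s03"), icfg)
  expect_equal(post$not_imputable, "s03")
  expect_equal(post$masked_ids, "s02")
  # s03 in the scaffold: fatal
  expect_error(impute_masked(st, "s02", icfg), "not imputable")
})

test_that("allele mismatches between study and reference are errors", {
  set.seed(9)
  panel <- toy_panel(matrix(rbinom(12, 1, 0.5), 4, 3))
  truth <- list(hap1 = matrix(0L, 2, 3), hap2 = matrix(0L, 2, 3))
  st <- cohort_study(matrix(0L, 2, 3), matrix(0L, 2, 3), panel$sites,
                     truth = list(cases = truth, controls = truth))
  flipped <- panel
  flipped$sites$ref_allele[2] <- "T"  # strand/allele disagreement
  expect_error(impute_masked(st, "s01", imputation_config(flipped)),
               "allele mismatch")
})

test_that("genotype calling honours the threshold and tie rules", {
  arr <- array(NA_real_, c(3, 1, 3))
  arr[1, 1, ] <- c(0.95, 0.03, 0.02)
  arr[2, 1, ] <- c(0.50, 0.40, 0.10)
  arr[3, 1, ] <- c(0.45, 0.45, 0.10)
  expect_equal(unname(call_genotypes(arr, 0.9)[, 1]), c(0L, NA, NA))
  expect_equal(unname(call_genotypes(arr, 0.5)[, 1]), c(0L, 0L, NA))  # tie -> missing
  expect_equal(unname(call_genotypes(arr, 0)[, 1]), c(0L, 0L, 0L))   # never missing
})

test_that("calling is monotone in the threshold", {
  set.seed(3)
  arr <- array(runif(60), c(10, 2, 3))
  arr <- arr / rep(apply(arr, 1:2, sum), 3)
  miss <- function(t) sum(is.na(call_genotypes(arr, t)))
  thr <- sort(runif(5))
  expect_true(all(diff(vapply(thr, miss, numeric(1))) >= 0))
})

test_that("info score closed forms hold", {
  mk <- function(tri, n) {
    a <- array(NA_real_, c(n, 1, 3))
    for (i in seq_len(n)) a[i, 1, ] <- tri
    list(cases = a, controls = a[0, , , drop = FALSE], masked_ids = "m1")
  }
  expect_equal(info_score(mk(c(0, 0, 1), 5), 1), 1)   # degenerate -> 1
  expect_equal(info_score(mk(c(1, 0, 0), 5), 1), 1)   # theta = 0 boundary
  # N = 2 of (0.25, 0.5, 0.25): e = 1, f = 1.5, theta = 0.5 -> info = 0
  expect_equal(info_score(mk(c(0.25, 0.5, 0.25), 2), 1), 0)
  # mixed case stays below 1
  m <- mk(c(0.5, 0.5, 0), 4)
  m$cases[1, 1, ] <- c(0, 0, 1)
  expect_lt(info_score(m, 1), 1)
})

test_that("posterior triples normalise and epsilon default matches its formula", {
  cfg <- toy_sim(n_sites = 8, n_assoc = 2, seed = 19, n_cases = 10,
                 n_controls = 10, mutation = 0.01)
  st <- sample_cohort(cfg)
  ref <- sample_reference_panel(cfg)
  icfg <- imputation_config(ref)
  K <- nrow(ref$alleles)
  theta <- 1 / sum(1 / seq_len(K - 1))
  expect_equal(icfg$epsilon, theta / (2 * (K + theta)))
  post <- impute_masked(st, st$sites$id[st$sites$is_associated], icfg)
  sums <- apply(post$cases, 1:2, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(post$cases >= 0))
})
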