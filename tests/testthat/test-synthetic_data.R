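test_that("build_founders places risk alleles per architecture", {
  mono <- build_founders(4, 10, 3, "monophyletic", seed = 1)
  assoc <- which(mono$sites$is_associated)
  expect_length(assoc, 3)
  expect_true(all(mono$alleles[1, assoc] == 1))
  expect_true(all(mono$alleles[-1, assoc] == 0))
  # risk founder shares its background with founder 2
  expect_equal(mono$alleles[1, -assoc], mono$alleles[2, -assoc])

  poly <- build_founders(4, 10, 3, "polyphyletic", seed = 1)
  assoc <- which(poly$sites$is_associated)
  subs <- apply(poly$alleles[attr(poly, "risk_founders"), assoc, drop = FALSE],
                1, paste, collapse = "")
  expect_gte(length(unique(subs)), 2)
  expect_true(all(nchar(gsub("0", "", subs)) > 0))   # non-empty subsets
  expect_true(all(poly$alleles[3:4, assoc] == 0))

  # a larger monophyletic region: all risk alleles co-segregate on one founder
  big <- build_founders(6, 20, 8, "monophyletic", seed = 3)
  assoc <- which(big$sites$is_associated)
  carriers <- which(rowSums(big$alleles[, assoc, drop = FALSE]) > 0)
  expect_identical(carriers, 1L)
  expect_true(all(big$alleles[1, assoc] == 1))
})

test_that("build_founders rejects invalid configurations", {
  expect_error(build_founders(4, 5, 6, "monophyletic"), "invalid configuration")
  expect_error(build_founders(1, 5, 2, "monophyletic"), "invalid configuration")
  expect_error(build_founders(4, 5, 1, "polyphyletic"), "invalid configuration")
})

test_that("sample_reference_panel reproduces founders exactly without noise", {
  cfg <- toy_sim(mutation = 0, recomb = 0)
  ref <- sample_reference_panel(cfg)
  expect_equal(nrow(ref$alleles), cfg$n_reference_haps)
  keys <- apply(cfg$founders$alleles, 1, paste, collapse = "")
  expect_true(all(apply(ref$alleles, 1, paste, collapse = "") %in% keys))
})

test_that("sampled founder frequencies land within 3 binomial SE", {
  freqs <- c(0.1, 0.3, 0.4, 0.2)
  cfg <- toy_sim(n_ref = 1000, freq_ref = freqs, mutation = 0, recomb = 0,
                 seed = 11)
  ref <- sample_reference_panel(cfg)
  emp <- tabulate(attr(ref, "origin"), 4) / 1000
  se <- sqrt(freqs * (1 - freqs) / 1000)
  expect_true(all(abs(emp - freqs) <= 3 * se))
})

test_that("identical seeds give identical draws, different seeds differ", {
  cfg <- toy_sim(seed = 5, mutation = 0.01, recomb = 0.05)
  expect_identical(sample_reference_panel(cfg)$alleles,
                   sample_reference_panel(cfg)$alleles)
  s1 <- sample_cohort(cfg); s2 <- sample_cohort(cfg)
  expect_identical(s1$cases, s2$cases)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- toy_sim(seed = 6, mutation = 0.01, recomb = 0.05)
  expect_false(identical(sample_cohort(cfg2)$cases, s1$cases))
})

test_that("genotypes are the column-wise sum of truth haplotypes", {
  cfg <- toy_sim(mutation = 0, recomb = 0)
  st <- sample_cohort(cfg)
  expect_identical(st$cases, {
    g <- st$truth$cases$hap1 + st$truth$cases$hap2
    rownames(g) <- rownames(st$cases); colnames(g) <- colnames(st$cases)
    storage.mode(g) <- "integer"; g
  })
  # and with noise the identity still holds (noise applies to haplotypes)
  cfgn <- toy_sim(mutation = 0.05, recomb = 0.1, seed = 9)
  stn <- sample_cohort(cfgn)
  expect_true(all(stn$cases == stn$truth$cases$hap1 + stn$truth$cases$hap2))
})

test_that("case risk-haplotype counts follow the binomial oracle", {
  cfg <- toy_sim(n_cases = 92, freq_cases = c(0.25, 0.25, 0.25, 0.25))
  cfg$founder_freqs_cases <- c(0.25, 0.35, 0.2, 0.2)
  st <- sample_cohort(cfg)
  n_risk <- sum(attr(st, "origin")$cases == 1)
  se <- sqrt(0.25 * 0.75 / 184)
  expect_lt(abs(n_risk / 184 - 0.25), 3 * se + 1e-12)
})

test_that("empirical risk-haplotype frequency converges at n = 5000", {
  cfg <- toy_sim(n_cases = 5000, n_controls = 2,
                 freq_cases = c(0.25, 0.35, 0.2, 0.2), seed = 13)
  st <- sample_cohort(cfg)
  expect_lt(abs(mean(attr(st, "origin")$cases == 1) - 0.25), 0.02)
})

test_that("degenerate single-founder cohort is homozygous everywhere", {
  cfg <- toy_sim(freq_cases = c(1, 0, 0, 0), mutation = 0, recomb = 0)
  st <- sample_cohort(cfg)
  expect_true(all(st$cases %in% c(0L, 2L)))
  expect_true(all(t(st$cases) / 2 == cfg$founders$alleles[1, ]))
})

test_that("invalid cohort sizes and frequency vectors are rejected", {
  cfg <- toy_sim()
  cfg$n_cases <- 0L
  expect_error(sample_cohort(cfg), "invalid configuration")
  expect_error(simulation_config(toy_sim()$founders, c(0.5, 0.5), rep(0.25, 4),
                                 rep(0.25, 4), 10, 5, 5),
               "invalid configuration")
  expect_error(simulation_config(toy_sim()$founders, rep(0.3, 4), rep(0.25, 4),
                                 rep(0.25, 4), 10, 5, 5),
               "sum")
})
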