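small_cfg <- function(...) {
  cohort_config(n_chroms = 1L, gus_per_chrom = 300L, ...)
}

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(small_cfg(seed = 7))
  b <- simulate_cohort(small_cfg(seed = 7))
  expect_identical(a, b)
  c_ <- simulate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$ref_comparisons, c_$ref_comparisons))
})

test_that("cohort structure matches its configuration", {
  cfg <- small_cfg(seed = 9, n_ref = 3L, n_test = 2L, planted_fraction = 0.2)
  coh <- simulate_cohort(cfg)
  expect_equal(length(coh$ref_comparisons), 3L)  # choose(3, 2)
  expect_equal(length(coh$test_comparisons), 2L)
  expect_equal(nrow(coh$gus), 300L)
  expect_true(all(coh$gus$end - coh$gus$start == cfg$gu_width))
  # truth labels partition features exactly
  expect_equal(sum(coh$features$planted),
               round(0.2 * nrow(coh$features)))
  expect_true(all(coh$features$planted %in% c(TRUE, FALSE)))
  # JSD tracks only contain GUs with data in both samples, values in [0, 1]
  for (tr in c(coh$ref_comparisons, coh$test_comparisons)) {
    expect_true(all(tr$jsd >= 0 & tr$jsd <= 1))
    expect_lte(nrow(tr), 300L)
  }
  # MML/NME tracks in [0, 1]
  expect_true(all(coh$mml$ref1$value >= 0 & coh$mml$ref1$value <= 1))
  expect_true(all(coh$nme$ref1$value >= 0 & coh$nme$ref1$value <= 1))
})

test_that("masking removes GUs from every comparison involving the sample", {
  coh <- simulate_cohort(small_cfg(seed = 10, missing_fraction = 0.2))
  n_pmf <- sum(!vapply(coh$pmfs$ref1, is.null, logical(1)))
  expect_lt(n_pmf, 300L)
  expect_lte(nrow(coh$ref_comparisons$ref1_vs_ref2), n_pmf)
})

test_that("planted features inflate test/reference JSDs", {
  coh <- simulate_cohort(small_cfg(seed = 11, planted_fraction = 0.3,
                                   effect_size = 3))
  ref_jsd <- coh$ref_comparisons[[1]]$jsd
  test_jsd <- coh$test_comparisons[[1]]$jsd
  # reference/reference JSDs are stochastically smaller
  w <- wilcox.test(test_jsd, ref_jsd, alternative = "greater")
  expect_lt(w$p.value, 1e-6)
})

test_that("a null cohort has no planted signal", {
  coh <- simulate_cohort(small_cfg(seed = 12, planted_fraction = 0))
  expect_equal(sum(coh$features$planted), 0L)
  w <- wilcox.test(coh$test_comparisons[[1]]$jsd,
                   coh$ref_comparisons[[1]]$jsd)
  expect_gt(w$p.value, 0.01)
})

test_that("direct (t, s) draws match the analytic distribution", {
  surf <- list(mu = function(s) -2.5 + 0.1 * s, sigma = 0.5, nu = 1.3,
               tau = 6)
  obs <- simulate_null_observations(surf, n = 5000,
                                    s_range = c(4.95, 5.05), seed = 13)
  expect_true(all(obs$s >= 4.95 & obs$s <= 5.05))
  ks <- ks.test(obs$t, function(q) plogitsst(q, -2.5 + 0.1 * 5, 0.5, 1.3, 6))
  expect_gt(ks$p.value, 0.01)
  # determinism
  expect_identical(obs, simulate_null_observations(surf, n = 5000,
                                                   s_range = c(4.95, 5.05),
                                                   seed = 13))
  expect_error(simulate_null_observations(list(mu = 1), 10), "surface")
  expect_error(
    simulate_null_observations(list(mu = 0, sigma = -1, nu = 1, tau = 5),
                               10, seed = 1), "sigma")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(cohort_config(planted_fraction = 1.5))
  expect_error(cohort_config(n_ref = 1L))
  expect_error(cohort_config(cpgs_per_gu = c(5L, 2L)))
  expect_error(simulate_cohort(list()), "cohort_config")
})
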