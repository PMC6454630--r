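test_that("Fisher's promoter/body statistic has its closed-form values", {
  expect_equal(fisher_pb(1, 1), 0)
  expect_equal(fisher_pb(exp(-1), exp(-1)), 4)
  expect_equal(fisher_pb(0.05, 0.2), -2 * log(0.01), tolerance = 1e-12)
  expect_true(is.na(fisher_pb(NA, 0.5)))
  expect_error(fisher_pb(0, 0.5), "\\(0, 1\\]")
})

test_that("empirical null p-values follow the Iverson-bracket CDF", {
  nn <- empirical_null(c(1, 2, 3, 4))
  expect_equal(empirical_pb_pvalue(2.5, nn), 0.5)
  expect_equal(empirical_pb_pvalue(0.5, nn), 1)
  # above all observations: clamped at 1 / (N_r + 1)
  expect_equal(empirical_pb_pvalue(10, nn), 0.2)
  expect_equal(empirical_pb_pvalue(c(1, 4), nn), c(0.75, 0.2))
  expect_error(empirical_null(numeric(0)), "at least one")
  expect_error(empirical_null(c(1, -2)), "nonnegative")
})

test_that("chi-squared upper tails match the even-df closed forms", {
  # df = 2: exp(-t/2); df = 4: exp(-t/2) (1 + t/2)
  t1 <- -2 * log(0.05)
  expect_equal(chi2_fisher_pvalue(t1, 2), 0.05, tolerance = 1e-12)
  t2 <- -2 * log(0.01)
  expect_equal(chi2_fisher_pvalue(t2, 4), exp(-t2 / 2) * (1 + t2 / 2),
               tolerance = 1e-12)
  expect_equal(chi2_fisher_pvalue(0, 8), 1)
  expect_error(chi2_fisher_pvalue(1, 3), "even")
  expect_error(chi2_fisher_pvalue(1, 0), "even")
})

test_that("multi-comparison Fisher combination uses 2 N_t degrees of freedom", {
  one <- fisher_mult(0.05)
  expect_equal(one$t_mult, -2 * log(0.05))
  expect_equal(one$p, 0.05, tolerance = 1e-12)
  expect_equal(fisher_mult(c(1, 1, 1))$p, 1)
  two <- fisher_mult(c(0.05, 0.2))
  expect_equal(two$t_mult, -2 * log(0.01), tolerance = 1e-12)
  expect_equal(two$p, chi2_fisher_pvalue(-2 * log(0.01), 4))
  expect_error(fisher_mult(numeric(0)), "at least one")
})

test_that("rank products are geometric means of per-comparison ranks", {
  expect_equal(rank_products(matrix(c(2, 8), 1)), 4)
  expect_equal(rank_products(matrix(1:3, 3, 1)), c(1, 2, 3))
  rmat <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(order(rank_products(rmat)), order(rmat[, 1]))
  expect_error(rank_products(matrix(c(1, 0), 1)), ">= 1")
})

test_that("BH q-values reproduce the step-up worked example", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_qvalues(rep(1, 4)), rep(1, 4))
  expect_equal(bh_qvalues(0.37), 0.37)
})

test_that("assembled rankings sort by p and break ties by rank product", {
  # X and Y have identical Fisher products; W is clearly worse
  pmat <- rbind(X = c(0.2, 0.8), Y = c(0.4, 0.4), W = c(0.3, 0.9))
  tb <- assemble_ranking(pmat)
  expect_equal(tb$feature_id, c("X", "Y", "W"))
  expect_equal(tb$p[1], tb$p[2])
  expect_lt(tb$rank_product[1], tb$rank_product[2])
  expect_equal(tb$rank, 1:3)
  # q-values are monotone along the sorted table
  expect_true(all(diff(tb$q) >= -1e-12))
  # deterministic on identical input
  expect_identical(assemble_ranking(pmat), tb)
  # identical rows fall back to the feature id
  pm2 <- rbind(b = c(0.1, 0.2), a = c(0.1, 0.2))
  expect_equal(assemble_ranking(pm2)$feature_id, c("a", "b"))
})

test_that("features missing a p-value are dropped from the combined list", {
  pmat <- rbind(A = c(0.1, 0.2), B = c(NA, 0.3), C = c(0.5, 0.6))
  expect_message(tb <- assemble_ranking(pmat), "dropped")
  expect_equal(sort(tb$feature_id), c("A", "C"))
})

test_that("empirical Fisher null converges to chi2_4 under independence", {
  set.seed(51)
  n <- 20000
  null <- empirical_null(fisher_pb(runif(n), runif(n)))
  grid <- seq(0, 20, by = 0.5)
  gap <- abs(empirical_pb_pvalue(grid, null) -
               chi2_fisher_pvalue(grid, 4))
  expect_lt(max(gap), 0.02)
})

test_that("with correlated inputs only the empirical null stays calibrated", {
  set.seed(52)
  rho <- 0.8
  draw_tpb <- function(n) {
    z <- rnorm(n)
    u1 <- pnorm(rho * z + sqrt(1 - rho^2) * rnorm(n))
    u2 <- pnorm(rho * z + sqrt(1 - rho^2) * rnorm(n))
    fisher_pb(u1, u2)
  }
  null <- empirical_null(draw_tpb(50000))
  tpb <- draw_tpb(5000)
  p_emp <- empirical_pb_pvalue(tpb, null)
  p_chi <- chi2_fisher_pvalue(tpb, 4)
  # the empirical CDF has finite resolution, so exact ties are expected
  expect_gt(suppressWarnings(ks.test(p_emp, "punif"))$p.value, 0.01)
  expect_lt(ks.test(p_chi, "punif")$p.value, 0.01)
})

test_that("promoter/body combination plumbing aligns features and pairs", {
  set.seed(53)
  pp <- matrix(runif(40), 10)
  pb <- matrix(runif(40), 10)
  nn <- build_pb_null(pp, pb)
  expect_equal(nn$n, 40)
  p <- pb_pvalues(c(0.5, NA), c(0.5, 0.5), nn)
  expect_false(is.na(p[1]))
  expect_true(is.na(p[2]))
  expect_error(build_pb_null(pp, pb[1:5, ]), "identical shape")
})
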