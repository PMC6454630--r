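test_that("jsd matches direct evaluation of the divergence", {
  # p = (1/2, 1/2) vs q = (1, 0), base-2: KL(p||m) + KL(q||m) terms by hand
  m <- c(0.75, 0.25)
  d2 <- 0.5 * (0.5 * log2(0.5 / m[1]) + 0.5 * log2(0.5 / m[2])) +
    0.5 * (1 * log2(1 / m[1]))
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), sqrt(d2), tolerance = 1e-12)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.5579230, tolerance = 1e-6)
})

test_that("jsd attains its bounds and rejects mismatched supports", {
  set.seed(11)
  p <- random_pmf(4)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0, 0), c(0, 0, 1)), 1)  # disjoint supports: 1 bit
  expect_error(jsd(c(0.5, 0.5), c(1, 0, 0)), "mismatched supports")
})

test_that("jsd is a metric on random PMF triples", {
  set.seed(12)
  for (rep in 1:500) {
    L <- sample(1:5, 1)
    p <- random_pmf(L); q <- random_pmf(L); r <- random_pmf(L)
    dpq <- jsd(p, q); dpr <- jsd(p, r); dqr <- jsd(q, r)
    expect_equal(dpq, jsd(q, p), tolerance = 1e-12)      # symmetry
    expect_gte(dpq, 0)
    expect_lte(dpq, 1)
    expect_gte(dpq + dpr - dqr, -1e-12)                  # triangle
  }
})

test_that("t_statistic is the RMS of the per-GU distances", {
  expect_equal(t_statistic(c(0, 0, 0)), 0)
  expect_equal(t_statistic(rep(1, 5)), 1)
  expect_equal(t_statistic(c(0.3, 0.4)), sqrt(0.125))
  expect_error(t_statistic(numeric(0)), "at least one")
  expect_error(t_statistic(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("T satisfies the triangle inequality across phenotypes", {
  set.seed(13)
  for (rep in 1:200) {
    K <- sample(1:4, 1)
    L <- sample(1:3, 1)
    q1 <- replicate(K, random_pmf(L), simplify = FALSE)
    q2 <- replicate(K, random_pmf(L), simplify = FALSE)
    q3 <- replicate(K, random_pmf(L), simplify = FALSE)
    tij <- function(a, b) {
      t_statistic(mapply(jsd, a, b))
    }
    expect_gte(tij(q1, q2) + tij(q1, q3) - tij(q2, q3), -1e-12)
  }
})

test_that("mutual information matches the direct double sum", {
  set.seed(14)
  for (rep in 1:50) {
    L <- sample(1:4, 1)
    p <- random_pmf(L); q <- random_pmf(L)
    prior <- runif(1, 0.05, 0.95)
    expect_equal(gu_mutual_information(p, q, prior), mi_oracle(p, q, prior),
                 tolerance = 1e-12)
  }
})

test_that("mutual information has the expected special values", {
  p <- random_pmf(3)
  expect_equal(gu_mutual_information(p, p, 0.3), 0)
  expect_equal(gu_mutual_information(c(1, 0), c(0, 1), 0.5), 1)  # 1 bit
  # uniform prior: MI equals the squared Jensen-Shannon distance
  expect_equal(gu_mutual_information(c(0.5, 0.5), c(1, 0), 0.5),
               jsd(c(0.5, 0.5), c(1, 0))^2, tolerance = 1e-12)
})

test_that("average MI at uniform prior equals the squared T statistic", {
  set.seed(15)
  for (rep in 1:50) {
    K <- sample(1:5, 1)
    L <- sample(1:3, 1)
    pairs <- replicate(K, list(random_pmf(L), random_pmf(L)),
                       simplify = FALSE)
    jsds <- vapply(pairs, function(pr) jsd(pr[[1]], pr[[2]]), numeric(1))
    expect_equal(average_mutual_information(pairs, 0.5),
                 t_statistic(jsds)^2, tolerance = 1e-10)
  }
  expect_error(average_mutual_information(list()), "non-empty")
})
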