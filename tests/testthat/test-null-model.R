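test_that("fitting requires enough strictly valid observations", {
  expect_error(fit_null_model(data.frame(t = runif(10), s = runif(10, 3, 5))),
               "insufficient observations")
  expect_error(fit_null_model(data.frame(t = c(rep(0.5, 600), 1.5),
                                         s = rep(3, 601))),
               "lie in \\[0, 1\\]")
  expect_error(fit_null_model(list(1, 2)), "data frame")
})

test_that("constant fit recovers its generating parameters and edf is 4", {
  obs <- simulate_null_observations(list(mu = -2, sigma = 0.5, nu = 1.2,
                                         tau = 5),
                                    n = 4000, s_range = c(3, 8), seed = 31)
  m <- fit_null_model(obs, null_fit_control(constant = TRUE))
  pars <- predict(m, 5)
  expect_equal(pars$mu, -2, tolerance = 0.1)
  expect_equal(log(pars$sigma), log(0.5), tolerance = 0.15)
  expect_equal(log(pars$nu), log(1.2), tolerance = 0.15)
  expect_equal(sum(m$edf), 4, tolerance = 1e-6)
  # AIC - BIC = 2 * edf - edf * log(n) for the 4-parameter fit
  ab <- model_aic_bic(m)
  expect_equal(ab$aic - ab$bic, 8 - 4 * log(m$n), tolerance = 1e-6)
})

test_that("stronger smoothing penalties shrink the effective df", {
  obs <- simulate_null_observations(list(mu = -1.5, sigma = 0.5, nu = 1,
                                         tau = 6),
                                    n = 1500, s_range = c(3, 8), seed = 32)
  edfs <- vapply(c(1, 100, 1e4, 1e6), function(lam) {
    m <- fit_null_model(obs, null_fit_control(n_knots = 8, lambda = lam,
                                              select_lambda = FALSE))
    sum(m$edf)
  }, numeric(1))
  expect_true(all(diff(edfs) < 0))
  expect_gt(edfs[1], edfs[4])
})

test_that("p-values, quantile residuals, and centiles are coherent", {
  m <- small_null_model()
  pars <- predict(m, 4)
  # by construction, the 95th percentile has p-value 0.05
  tq <- qlogitsst(0.95, pars$mu, pars$sigma, pars$nu, pars$tau)
  expect_equal(null_pvalue(tq, 4, m), 0.05, tolerance = 1e-6)
  expect_equal(null_pvalue(0, 4, m), 1)
  expect_equal(null_pvalue(1, 4, m), 0)
  expect_error(null_pvalue(1.2, 4, m), "\\[0, 1\\]")
  # residual at the conditional median is zero; residuals increase with t
  tmed <- qlogitsst(0.5, pars$mu, pars$sigma, pars$nu, pars$tau)
  g <- quantile_residuals(data.frame(t = c(tmed, 0.1, 0.2, 0.3, 0.4),
                                     s = 4), m)
  expect_equal(g[1], 0, tolerance = 1e-9)
  expect_true(all(diff(g[-1]) > 0))
  # centile curves are ordered at every grid point
  cc <- centile_curves(c(25, 75), m, seq(2, 6, length.out = 11))
  expect_true(all(cc$value[cc$alpha == 25] < cc$value[cc$alpha == 75]))
  expect_error(centile_curves(c(0, 50), m, 3), "strictly in")
})

test_that("sizes outside the training range are clamped", {
  m <- small_null_model()
  expect_equal(predict(m, 100)[, -1], predict(m, m$s_range[2])[, -1])
  expect_equal(null_pvalue(0.3, -5, m), null_pvalue(0.3, m$s_range[1], m))
})

test_that("a fitted model serializes to JSON and back without loss", {
  m <- small_null_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_null_model(m, path)
  m2 <- read_null_model(path)
  s <- seq(2, 6, length.out = 23)
  expect_equal(predict(m2, s), predict(m, s), tolerance = 1e-12)
  expect_equal(m2$edf, m$edf)
  expect_identical(m2$family, m$family)
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), other,
                       auto_unbox = TRUE)
  expect_error(read_null_model(other), "not a methrank")
})

test_that("the logitSST family beats a logit-normal baseline on skewed data", {
  obs <- simulate_null_observations(list(mu = -2, sigma = 0.6, nu = 2,
                                         tau = 4),
                                    n = 4000, s_range = c(3, 8), seed = 33)
  ctl <- null_fit_control(n_knots = 8, lambda = 1e4, select_lambda = FALSE)
  aic_sst <- model_aic_bic(fit_null_model(obs, ctl))$aic
  aic_no <- model_aic_bic(fit_null_model(obs, ctl, family = "logitNO"))$aic
  expect_lt(aic_sst, aic_no)
})
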