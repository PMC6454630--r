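# The logit skew-t (logitSST) family used as the size-dependent null for the
# T statistic: Y = 1 / (1 + exp(-X)) with X = mu + sigma * Z and Z a
# Fernandez-Steel skew-t with skewness nu > 0 and tail parameter tau > 2.
#
# Fernandez-Steel density: f(z; nu, tau) =
#   (2 / (nu + 1/nu)) * [ f_t(z/nu; tau) 1{z >= 0} + f_t(nu z; tau) 1{z < 0} ],
# which has the closed-form CDF
#   F(z) = 2/(nu^2+1) * F_t(nu z; tau)                      for z < 0,
#   F(z) = 1/(nu^2+1) + 2 nu^2/(nu^2+1) (F_t(z/nu; tau)-1/2) for z >= 0,
# so F(0) = 1/(nu^2+1) and nu = 1 recovers the symmetric Student t.

.check_sst_params <- function(mu, sigma, nu, tau) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) ||
      any(!is.finite(nu)) || any(!is.finite(tau))) {
    stop("logitSST parameters must be finite")
  }
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(nu <= 0)) stop("nu must be positive")
  if (any(tau <= 2)) stop("tau must exceed 2")
  invisible(TRUE)
}

.dsst <- function(z, nu, tau, log = FALSE) {
  lk <- log(2) - log(nu + 1 / nu)
  neg <- z < 0
  zz <- ifelse(neg, nu * z, z / nu)
  out <- lk + dt(zz, df = tau, log = TRUE)
  if (log) out else exp(out)
}

.psst <- function(z, nu, tau) {
  lo <- 2 / (nu^2 + 1) * pt(nu * z, df = tau)
  hi <- 1 / (nu^2 + 1) + (2 * nu^2 / (nu^2 + 1)) * (pt(z / nu, df = tau) - 0.5)
  ifelse(z < 0, lo, hi)
}

.qsst <- function(u, nu, tau) {
  u0 <- 1 / (nu^2 + 1)
  # both branch arguments clamped to [0, 1]: ifelse evaluates both sides,
  # and the discarded branch must not generate NaN warnings
  lo <- qt(pmin(pmax(u * (nu^2 + 1) / 2, 0), 1), df = tau) / nu
  hi <- nu * qt(pmin(pmax((u - u0) * (nu^2 + 1) / (2 * nu^2) + 0.5, 0), 1),
                df = tau)
  ifelse(u <= u0, lo, hi)
}

#' The logit skew-t (logitSST) distribution
#'
#' Density, distribution function, quantile function, and random generation
#' for the logistic transform \eqn{Y = 1/(1 + e^{-X})} of a location-scale
#' Fernandez-Steel skew Student's t variable \eqn{X = \mu + \sigma Z}. This is
#' the family used to model the null density \eqn{f_0(t; s)} of the T
#' statistic; \code{nu = 1} gives the symmetric logit-t, and
#' \eqn{F(\mathrm{logistic}(\mu)) = 1/(\nu^2 + 1)} for any \eqn{\sigma, \tau}.
#'
#' @param t Vector of values in (0, 1) (the closed endpoints are accepted by
#'   \code{plogitsst}, mapping to 0 and 1).
#' @param u Vector of probabilities in (0, 1).
#' @param n Number of random draws.
#' @param mu Location of \eqn{X} (logit scale).
#' @param sigma Scale of \eqn{X}, positive.
#' @param nu Skewness, positive; values > 1 skew right on the logit scale.
#' @param tau Tail parameter (degrees of freedom), must exceed 2.
#' @param log If TRUE, return the log density.
#' @return \code{dlogitsst} the density, \code{plogitsst} the CDF,
#'   \code{qlogitsst} the quantile (exact inverse of the CDF),
#'   \code{rlogitsst} random draws.
#' @name logitsst
#' @export
dlogitsst <- function(t, mu, sigma, nu, tau, log = FALSE) {
  .check_sst_params(mu, sigma, nu, tau)
  if (any(!is.finite(t)) || any(t <= 0) || any(t >= 1)) {
    stop("t must lie strictly in (0, 1)")
  }
  z <- (qlogis(t) - mu) / sigma
  out <- .dsst(z, nu, tau, log = TRUE) - log(sigma) - log(t) - log1p(-t)
  if (log) out else exp(out)
}

#' @rdname logitsst
#' @export
plogitsst <- function(t, mu, sigma, nu, tau) {
  .check_sst_params(mu, sigma, nu, tau)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("t must lie in [0, 1]")
  }
  out <- numeric(length(t))
  mu <- rep_len(mu, length(t)); sigma <- rep_len(sigma, length(t))
  nu <- rep_len(nu, length(t)); tau <- rep_len(tau, length(t))
  inner <- t > 0 & t < 1
  out[t <= 0] <- 0
  out[t >= 1] <- 1
  if (any(inner)) {
    z <- (qlogis(t[inner]) - mu[inner]) / sigma[inner]
    out[inner] <- .psst(z, nu[inner], tau[inner])
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname logitsst
#' @export
qlogitsst <- function(u, mu, sigma, nu, tau) {
  .check_sst_params(mu, sigma, nu, tau)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("u must lie strictly in (0, 1)")
  }
  plogis(mu + sigma * .qsst(u, nu, tau))
}

#' @rdname logitsst
#' @export
rlogitsst <- function(n, mu, sigma, nu, tau) {
  qlogitsst(runif(n), mu, sigma, nu, tau)
}
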