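# Size-dependent null model for the T statistic: f0(t; s) approximated by a
# logitSST distribution whose four parameter curves mu(s), ln sigma(s),
# ln nu(s), ln(tau(s) - 2) are smooth functions of the feature size
# s = log2(K), fitted to reference/reference observations (t_k, s_k) by
# penalized maximum likelihood (P-spline basis, cyclic backfitting with
# penalized Newton updates, per-curve smoothing parameters by AIC grid
# search). This is a heteroscedastic (GAMLSS-style) distributional
# regression: all distribution parameters, not just the mean, vary with s.

#' Control parameters for [fit_null_model()]
#'
#' @param n_knots Number of equally spaced interior knots of the cubic
#'   B-spline basis over the observed s-range (default 20; the basis then has
#'   \code{n_knots + 4} columns per curve).
#' @param lambda Optional fixed smoothing parameter(s), recycled over the
#'   parameter curves. When supplied, the AIC grid search is skipped unless
#'   \code{select_lambda = TRUE} is forced.
#' @param lambda_grid Candidate smoothing parameters for the per-curve AIC
#'   grid search (second-order difference penalty; large values shrink a
#'   curve toward a straight line in s).
#' @param select_lambda Whether to grid-search a smoothing parameter per
#'   curve by minimizing AIC (default: yes, unless \code{lambda} is given).
#' @param max_cycles Maximum backfitting cycles (default 200).
#' @param tol Convergence tolerance on the change in penalized log-likelihood
#'   between cycles (default 1e-6).
#' @param inner_steps Penalized Newton steps per curve within one cycle.
#' @param min_obs Minimum number of observations required to fit (default
#'   500).
#' @param eps Observations with t exactly 0 or 1 are nudged to
#'   \code{(eps, 1 - eps)} before fitting (non-inflated family).
#' @param constant If TRUE, fit size-independent parameters (an
#'   intercept-only basis with no penalty; 1 effective df per curve). Used
#'   for model comparison baselines.
#' @param verbose Print per-cycle progress.
#' @return A list of class \code{"null_fit_control"}.
#' @export
null_fit_control <- function(n_knots = 20L, lambda = NULL,
                             lambda_grid = 10^seq(-2, 6, by = 2),
                             select_lambda = is.null(lambda),
                             max_cycles = 200L, tol = 1e-6,
                             inner_steps = 2L, min_obs = 500L,
                             eps = 1e-6, constant = FALSE, verbose = FALSE) {
  stopifnot(n_knots >= 0, max_cycles >= 1, tol > 0, inner_steps >= 1,
            min_obs >= 1, eps > 0, eps < 0.5)
  structure(list(n_knots = as.integer(n_knots), lambda = lambda,
                 lambda_grid = lambda_grid, select_lambda = select_lambda,
                 max_cycles = as.integer(max_cycles), tol = tol,
                 inner_steps = as.integer(inner_steps),
                 min_obs = as.integer(min_obs), eps = eps,
                 constant = isTRUE(constant), verbose = isTRUE(verbose)),
            class = "null_fit_control")
}

# ---- families ---------------------------------------------------------------

# A family bundles the number of parameter curves, the link inverses, and the
# per-observation log-likelihood as a function of the linear predictors.
.null_family <- function(name) {
  switch(name,
    logitSST = list(
      name = "logitSST", npar = 4L,
      par_names = c("mu", "sigma", "nu", "tau"),
      links = c("identity", "log", "log", "logshift2"),
      linkinv = function(eta) {
        cbind(mu = eta[, 1L], sigma = exp(eta[, 2L]),
              nu = exp(eta[, 3L]), tau = 2 + exp(eta[, 4L]))
      },
      loglik = function(t, eta) {
        dlogitsst(t, eta[, 1L], exp(eta[, 2L]), exp(eta[, 3L]),
                  2 + exp(eta[, 4L]), log = TRUE)
      },
      cdf = function(t, pars) {
        plogitsst(t, pars[, 1L], pars[, 2L], pars[, 3L], pars[, 4L])
      },
      quantile = function(u, pars) {
        qlogitsst(u, pars[, 1L], pars[, 2L], pars[, 3L], pars[, 4L])
      },
      init = function(t) {
        x <- qlogis(t)
        c(mean(x), log(max(sd(x), 1e-3)), 0, log(8))
      }),
    logitNO = list(
      name = "logitNO", npar = 2L,
      par_names = c("mu", "sigma"),
      links = c("identity", "log"),
      linkinv = function(eta) {
        cbind(mu = eta[, 1L], sigma = exp(eta[, 2L]))
      },
      loglik = function(t, eta) {
        x <- qlogis(t)
        dnorm(x, eta[, 1L], exp(eta[, 2L]), log = TRUE) - log(t) - log1p(-t)
      },
      cdf = function(t, pars) {
        out <- numeric(length(t))
        out[t >= 1] <- 1
        i <- t > 0 & t < 1
        mu <- rep_len(pars[, 1L], length(t))
        si <- rep_len(pars[, 2L], length(t))
        out[i] <- pnorm(qlogis(t[i]), mu[i], si[i])
        out
      },
      quantile = function(u, pars) {
        plogis(qnorm(u, pars[, 1L], pars[, 2L]))
      },
      init = function(t) {
        x <- qlogis(t)
        c(mean(x), log(max(sd(x), 1e-3)))
      }),
    stop("unknown null family: ", name))
}

# ---- spline basis -----------------------------------------------------------

.basis_spec <- function(s, control) {
  s_lo <- min(s); s_hi <- max(s)
  ndist <- length(unique(round(s, 8)))
  # fixed-length features (e.g. promoters) yield only a handful of distinct
  # sizes; the basis cannot usefully be more flexible than that
  if (control$constant || s_hi - s_lo < 1e-8 || ndist <= 3L) {
    return(list(type = "constant", boundary = c(s_lo, s_hi),
                knots = numeric(0), degree = 0L, ncol = 1L))
  }
  nk <- min(control$n_knots, max(ndist - 4L, 0L))
  knots <- if (nk > 0) {
    seq(s_lo, s_hi, length.out = nk + 2L)[-c(1L, nk + 2L)]
  } else numeric(0)
  list(type = "bspline", boundary = c(s_lo, s_hi), knots = knots,
       degree = 3L, ncol = length(knots) + 4L)
}

.basis_eval <- function(spec, s) {
  s <- pmin(pmax(s, spec$boundary[1L]), spec$boundary[2L])
  if (spec$type == "constant") {
    return(matrix(1, length(s), 1L))
  }
  splines::bs(s, knots = spec$knots, degree = spec$degree,
              intercept = TRUE, Boundary.knots = spec$boundary)
}

.basis_penalty <- function(spec) {
  p <- spec$ncol
  if (spec$type == "constant" || p < 3L) {
    return(matrix(0, p, p))
  }
  D <- diff(diag(p), differences = 2L)
  crossprod(D)
}

# ---- penalized backfitting --------------------------------------------------

.pen_term <- function(beta, lambda, P) {
  0.5 * sum(vapply(seq_len(ncol(beta)), function(j) {
    lambda[j] * drop(crossprod(beta[, j], P %*% beta[, j]))
  }, numeric(1)))
}

# Numeric first/second derivatives of the per-observation log-likelihood with
# respect to one linear predictor. Non-positive curvatures (possible far from
# the optimum) are floored so the weighted solve stays positive definite.
.curve_derivs <- function(t, eta, j, fam, h = 1e-3) {
  ep <- eta; ep[, j] <- ep[, j] + h
  em <- eta; em[, j] <- em[, j] - h
  l0 <- fam$loglik(t, eta)
  lp <- fam$loglik(t, ep)
  lm <- fam$loglik(t, em)
  u <- (lp - lm) / (2 * h)
  w <- -(lp - 2 * l0 + lm) / h^2
  u[!is.finite(u)] <- 0
  bad <- !is.finite(w) | w <= 0
  flo <- if (all(bad)) 1e-3 else max(median(w[!bad]) * 1e-3, 1e-6)
  w[bad] <- flo
  w <- pmax(w, flo)
  list(u = u, w = w, ll = sum(l0))
}

# One penalized Newton update of curve j with a backtracking line search on
# the true penalized log-likelihood; the update is strictly monotone — if no
# step along the direction improves the objective, the curve is left
# unchanged (so backfitting terminates cleanly once no curve can improve).
.newton_curve <- function(t, B, P, beta, lambda, j, fam) {
  eta <- B %*% beta
  d <- .curve_derivs(t, eta, j, fam)
  # working response z = eta_j + u/w; form w*z as w*eta_j + u directly so the
  # solve sees the exact score even where the curvature has been floored
  M <- crossprod(B, d$w * B) + lambda[j] * P
  rhs <- crossprod(B, d$w * eta[, j] + d$u)
  bj <- tryCatch(drop(solve(M, rhs)), error = function(e) {
    drop(solve(M + diag(1e-8, ncol(B)), rhs))
  })
  old <- beta[, j]
  if (any(!is.finite(bj))) return(beta)
  bj <- pmin(pmax(bj, -30), 30)
  f0 <- d$ll - .pen_term(beta, lambda, P)
  for (half in 0:12) {
    beta[, j] <- old + (bj - old) / 2^half
    fc <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
    if (is.finite(fc) && fc >= f0) return(beta)
  }
  beta[, j] <- old
  beta
}

# Refit a single curve to (near) convergence at a fixed smoothing parameter,
# holding the other curves fixed; used when comparing candidate lambdas so
# their likelihoods are evaluated at their own optima.
.fit_curve <- function(t, B, P, beta, lambda, j, fam, max_steps = 25L,
                       tol = 1e-3) {
  pll <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
  for (k in seq_len(max_steps)) {
    beta <- .newton_curve(t, B, P, beta, lambda, j, fam)
    new <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
    if (abs(new - pll) < tol) break
    pll <- new
  }
  beta
}

# One joint penalized Newton step over all curves at once. Coordinate-wise
# backfitting crawls when parameter curves trade off along a likelihood
# ridge (mu against nu, sigma against tau); the full cross-curve Hessian
# removes those slow modes. Mixed second derivatives are numeric, like the
# per-curve ones. Strictly monotone: the step is rejected if no backtracked
# fraction of it improves the penalized log-likelihood.
.joint_newton <- function(t, B, P, beta, lambda, fam, h = 1e-3) {
  npar <- fam$npar
  p <- ncol(B)
  eta <- B %*% beta
  shift <- function(d) {
    e <- eta
    for (j in seq_len(npar)) e[, j] <- e[, j] + d[j] * h
    fam$loglik(t, e)
  }
  l0 <- fam$loglik(t, eta)
  lp <- lm <- vector("list", npar)
  for (j in seq_len(npar)) {
    d <- numeric(npar)
    d[j] <- 1
    lp[[j]] <- shift(d)
    d[j] <- -1
    lm[[j]] <- shift(d)
  }
  g <- numeric(p * npar)
  W <- array(0, c(length(t), npar, npar))
  for (j in seq_len(npar)) {
    u <- (lp[[j]] - lm[[j]]) / (2 * h)
    u[!is.finite(u)] <- 0
    idx <- (j - 1L) * p + seq_len(p)
    g[idx] <- crossprod(B, u) - lambda[j] * (P %*% beta[, j])
    wjj <- -(lp[[j]] - 2 * l0 + lm[[j]]) / h^2
    wjj[!is.finite(wjj)] <- 0
    W[, j, j] <- wjj
  }
  for (j in seq_len(npar - 1L)) {
    for (k in (j + 1L):npar) {
      d <- numeric(npar)
      d[c(j, k)] <- 1
      lpp <- shift(d)
      d[c(j, k)] <- -1
      lmm <- shift(d)
      wjk <- -(lpp - lp[[j]] - lp[[k]] + 2 * l0 - lm[[j]] - lm[[k]] +
                 lmm) / (2 * h^2)
      wjk[!is.finite(wjk)] <- 0
      W[, j, k] <- W[, k, j] <- wjk
    }
  }
  H <- matrix(0, p * npar, p * npar)
  for (j in seq_len(npar)) {
    for (k in seq_len(npar)) {
      blk <- crossprod(B, W[, j, k] * B)
      if (j == k) blk <- blk + lambda[j] * P
      H[(j - 1L) * p + seq_len(p), (k - 1L) * p + seq_len(p)] <- blk
    }
  }
  f0 <- sum(l0) - .pen_term(beta, lambda, P)
  for (ridge in c(0, 1e-6, 1e-2, 1)) {
    delta <- tryCatch(
      solve(H + diag(ridge * (1 + abs(diag(H))), nrow(H)), g),
      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) next
    for (half in 0:10) {
      cand <- beta + matrix(delta / 2^half, p, npar)
      cand <- pmin(pmax(cand, -30), 30)
      fc <- sum(fam$loglik(t, B %*% cand)) - .pen_term(cand, lambda, P)
      if (is.finite(fc) && fc > f0) {
        return(list(beta = cand, pll = fc, moved = TRUE))
      }
    }
  }
  list(beta = beta, pll = f0, moved = FALSE)
}

.backfit <- function(t, B, P, beta, lambda, fam, control) {
  pll_old <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
  converged <- FALSE
  cycles <- 0L
  stall <- max(control$tol, 1e-3)
  for (cyc in seq_len(control$max_cycles)) {
    cycles <- cyc
    for (j in seq_len(fam$npar)) {
      for (k in seq_len(control$inner_steps)) {
        beta <- .newton_curve(t, B, P, beta, lambda, j, fam)
      }
    }
    pll <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
    if (control$verbose) {
      message(sprintf("  cycle %3d: penalized loglik %.6f", cyc, pll))
    }
    if (abs(pll - pll_old) < control$tol) {
      converged <- TRUE
      pll_old <- pll
      break
    }
    if (abs(pll - pll_old) < stall) {
      # backfitting has stalled on a cross-curve ridge: polish with joint
      # Newton steps, which converge quadratically near the optimum
      pll_old <- pll
      for (it in seq_len(50L)) {
        jn <- .joint_newton(t, B, P, beta, lambda, fam)
        beta <- jn$beta
        if (control$verbose) {
          message(sprintf("  joint %2d: penalized loglik %.6f", it, jn$pll))
        }
        if (!jn$moved || abs(jn$pll - pll_old) < control$tol) {
          converged <- TRUE
          break
        }
        pll_old <- jn$pll
      }
      pll_old <- sum(fam$loglik(t, B %*% beta)) - .pen_term(beta, lambda, P)
      if (converged) break
    } else {
      pll_old <- pll
    }
  }
  list(beta = beta, lambda = lambda, pll = pll_old,
       loglik = sum(fam$loglik(t, B %*% beta)),
       converged = converged, cycles = cycles)
}

# Effective degrees of freedom of each curve's smoother at the current fit:
# trace of (B'WB + lambda P)^{-1} B'WB.
.edf_curves <- function(t, B, P, beta, lambda, fam) {
  eta <- B %*% beta
  vapply(seq_len(fam$npar), function(j) {
    d <- .curve_derivs(t, eta, j, fam)
    BtWB <- crossprod(B, d$w * B)
    M <- BtWB + lambda[j] * P
    H <- tryCatch(solve(M, BtWB), error = function(e) {
      solve(M + diag(1e-8, ncol(B)), BtWB)
    })
    sum(diag(H))
  }, numeric(1))
}

.as_obs <- function(obs) {
  if (is.matrix(obs)) obs <- as.data.frame(obs)
  if (!is.data.frame(obs) || !all(c("t", "s") %in% names(obs))) {
    stop("obs must be a data frame with columns 't' and 's'")
  }
  obs
}

#' Fit the size-dependent null model of the T statistic
#'
#' Fits \eqn{\hat f_0(t; s)}, the null density of the T statistic as a
#' function of feature size \eqn{s = \log_2 K}, to observations \eqn{(t_k,
#' s_k)} collected from reference/reference comparisons. All distribution
#' parameters are smooth P-spline functions of s, estimated by penalized
#' maximum likelihood via cyclic backfitting (each curve updated in turn by a
#' penalized Newton step holding the others fixed) until the penalized
#' log-likelihood stabilizes. Per-curve smoothing parameters are chosen by a
#' grid search minimizing AIC unless fixed in \code{control}.
#'
#' @param obs Data frame with columns \code{t} (statistic values in \[0, 1\];
#'   exact 0/1 are nudged inward by \code{control$eps}) and \code{s} (sizes).
#' @param control A [null_fit_control()] list.
#' @param family \code{"logitSST"} (default) or the simpler \code{"logitNO"}
#'   (logit-normal) baseline for model comparison.
#' @return An object of class \code{"methyl_null_model"} with the fitted
#'   coefficient matrix, basis specification, smoothing parameters, per-curve
#'   effective degrees of freedom, log-likelihood, and training s-range
#'   (predictions clamp s to this range).
#' @seealso [null_pvalue()], [quantile_residuals()], [centile_curves()],
#'   [model_aic_bic()]
#' @export
fit_null_model <- function(obs, control = null_fit_control(),
                           family = c("logitSST", "logitNO")) {
  family <- match.arg(family)
  fam <- .null_family(family)
  obs <- .as_obs(obs)
  n <- nrow(obs)
  if (n < control$min_obs) {
    stop("insufficient observations: ", n, " < ", control$min_obs)
  }
  t <- as.numeric(obs$t)
  s <- as.numeric(obs$s)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("t values must lie in [0, 1]")
  }
  if (any(!is.finite(s))) stop("s values must be finite")
  t <- pmin(pmax(t, control$eps), 1 - control$eps)

  spec <- .basis_spec(s, control)
  B <- .basis_eval(spec, s)
  P <- .basis_penalty(spec)
  npar <- fam$npar

  # start smooth and let the AIC search relax curves that need flexibility;
  # starting wiggly risks locking curves into mutually compensating noise
  lambda <- control$lambda
  if (is.null(lambda)) lambda <- 1e4
  lambda <- rep_len(as.numeric(lambda), npar)
  if (spec$type == "constant") lambda[] <- 0

  # deterministic initialization: constant curves from pooled moments; the
  # B-spline basis is a partition of unity so a constant c is coef == c
  beta <- matrix(rep(fam$init(t), each = ncol(B)), ncol(B), npar)

  fit <- .backfit(t, B, P, beta, lambda, fam, control)

  if (control$select_lambda && spec$type != "constant") {
    for (pass in 1:2) {
      for (j in seq_len(npar)) {
        best <- NULL
        for (lam in control$lambda_grid) {
          lj <- fit$lambda
          lj[j] <- lam
          bj <- .fit_curve(t, B, P, fit$beta, lj, j, fam)
          ll <- sum(fam$loglik(t, B %*% bj))
          edf <- .edf_curves(t, B, P, bj, lj, fam)
          aic <- -2 * ll + 2 * sum(edf)
          if (is.null(best) || aic < best$aic - 1e-8) {
            best <- list(aic = aic, lam = lam, beta = bj)
          }
        }
        fit$lambda[j] <- best$lam
        fit$beta <- best$beta
      }
    }
    fit <- .backfit(t, B, P, fit$beta, fit$lambda, fam, control)
  }

  edf <- .edf_curves(t, B, P, fit$beta, fit$lambda, fam)
  model <- structure(list(
    family = family, par_names = fam$par_names, basis = spec,
    coef = fit$beta, lambda = fit$lambda, s_range = spec$boundary,
    edf = edf, loglik = fit$loglik, n = n, cycles = fit$cycles,
    converged = fit$converged, control = control), class = "methyl_null_model")

  if (!fit$converged) {
    cond <- structure(
      class = c("methrank_nonconvergence", "error", "condition"),
      list(message = paste0("null model fit did not converge within ",
                            control$max_cycles, " cycles (last penalized ",
                            "log-likelihood change above ", control$tol, ")"),
           call = sys.call(-1), model = model))
    stop(cond)
  }
  model
}

#' @export
print.methyl_null_model <- function(x, ...) {
  cat(sprintf("%s null model: n = %d, s in [%.3f, %.3f]\n",
              x$family, x$n, x$s_range[1], x$s_range[2]))
  cat(sprintf("  log-likelihood %.2f, total edf %.2f (%s)\n", x$loglik,
              sum(x$edf), paste(sprintf("%s %.1f", x$par_names, x$edf),
                                collapse = ", ")))
  cat(sprintf("  converged in %d backfitting cycles; lambda = %s\n",
              x$cycles, paste(format(x$lambda, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Evaluate the fitted parameter curves at given sizes
#'
#' @param object A fitted [fit_null_model()] object.
#' @param s Sizes at which to evaluate (clamped to the training range).
#' @param ... Unused.
#' @return Data frame with \code{s} and one column per distribution
#'   parameter (natural scale: \code{sigma}, \code{nu} positive, \code{tau}
#'   > 2).
#' @export
predict.methyl_null_model <- function(object, s, ...) {
  fam <- .null_family(object$family)
  s <- as.numeric(s)
  sc <- pmin(pmax(s, object$s_range[1L]), object$s_range[2L])
  B <- .basis_eval(object$basis, sc)
  pars <- fam$linkinv(B %*% object$coef)
  data.frame(s = s, pars)
}

.model_params <- function(model, s) {
  as.matrix(predict(model, s)[, model$par_names, drop = FALSE])
}

#' p-value of an observed T statistic under the fitted null
#'
#' \eqn{p(s) = \int_{t_*}^1 \hat f_0(t; s)\,dt = 1 - \hat F_0(t_*; s)}, with
#' the size clamped to the training range of the model.
#'
#' @param t_star Observed statistic value(s) in \[0, 1\].
#' @param s Feature size(s) \eqn{\log_2 K}; recycled against \code{t_star}.
#' @param model A fitted [fit_null_model()] object.
#' @return p-values in \[0, 1\].
#' @export
null_pvalue <- function(t_star, s, model) {
  if (!inherits(model, "methyl_null_model")) {
    stop("model must be a fitted 'methyl_null_model'")
  }
  if (any(!is.finite(t_star)) || any(t_star < 0) || any(t_star > 1)) {
    stop("t_star must lie in [0, 1]")
  }
  k <- max(length(t_star), length(s))
  t_star <- rep_len(t_star, k)
  s <- rep_len(s, k)
  fam <- .null_family(model$family)
  pars <- .model_params(model, s)
  pmin(pmax(1 - fam$cdf(t_star, pars), 0), 1)
}

#' Normalized quantile residuals of the fitted null model
#'
#' \eqn{g_k = \Phi^{-1}(\hat F_0(t_k; s_k))}: if the fitted model matches the
#' data-generating distribution, the residuals are standard normal draws.
#' CDF values are clipped to \code{[1e-12, 1 - 1e-12]} before inversion so
#' residuals are always finite.
#'
#' @param obs Data frame with columns \code{t} and \code{s}.
#' @param model A fitted [fit_null_model()] object.
#' @return Numeric vector of residuals, one per observation.
#' @export
quantile_residuals <- function(obs, model) {
  obs <- .as_obs(obs)
  fam <- .null_family(model$family)
  pars <- .model_params(model, obs$s)
  u <- fam$cdf(pmin(pmax(obs$t, 0), 1), pars)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Centile curves of the fitted null model
#'
#' The \eqn{\alpha}-centile curve at size s is the \eqn{\alpha/100} quantile
#' of \eqn{\hat f_0(\cdot; s)}; if the model is consistent with the data,
#' \eqn{\alpha}\% of observations fall below it.
#'
#' @param alphas Centile levels in percent, each strictly in (0, 100).
#' @param model A fitted [fit_null_model()] object.
#' @param s_grid Sizes at which to evaluate the curves.
#' @return Data frame with columns \code{alpha}, \code{s}, \code{value}.
#' @export
centile_curves <- function(alphas, model, s_grid) {
  if (any(!is.finite(alphas)) || any(alphas <= 0) || any(alphas >= 100)) {
    stop("centile levels must lie strictly in (0, 100)")
  }
  fam <- .null_family(model$family)
  pars <- .model_params(model, s_grid)
  out <- lapply(alphas, function(a) {
    data.frame(alpha = a, s = s_grid, value = fam$quantile(a / 100, pars))
  })
  do.call(rbind, out)
}

#' Empirical coverage of a centile curve
#'
#' Percent of observations strictly below their size's \eqn{\alpha}-centile;
#' close agreement with \eqn{\alpha} indicates the fitted null is consistent
#' with the data.
#'
#' @param alpha Centile level in percent, strictly in (0, 100).
#' @param obs Data frame with columns \code{t} and \code{s}.
#' @param model A fitted [fit_null_model()] object.
#' @return Coverage in percent.
#' @export
centile_coverage <- function(alpha, obs, model) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 100) {
    stop("alpha must lie strictly in (0, 100)")
  }
  obs <- .as_obs(obs)
  fam <- .null_family(model$family)
  pars <- .model_params(model, obs$s)
  100 * mean(obs$t < fam$quantile(alpha / 100, pars))
}

#' AIC, BIC, and effective degrees of freedom of a fitted null model
#'
#' \eqn{AIC = -2\hat\ell + 2\,edf}, \eqn{BIC = -2\hat\ell + edf \ln n},
#' where the effective degrees of freedom sum the traces of the per-curve
#' smoother hat matrices. Smaller is better under either criterion; used to
#' compare candidate null families (e.g. logitSST against a logit-normal
#' baseline).
#'
#' @param model A fitted [fit_null_model()] object.
#' @param obs Optional data frame \code{(t, s)}; when supplied, the
#'   log-likelihood (and n) are recomputed on these observations instead of
#'   using the training fit.
#' @return A list with elements \code{aic}, \code{bic}, \code{edf},
#'   \code{loglik}, \code{n}.
#' @export
model_aic_bic <- function(model, obs = NULL) {
  if (!inherits(model, "methyl_null_model")) {
    stop("model must be a fitted 'methyl_null_model'")
  }
  fam <- .null_family(model$family)
  if (is.null(obs)) {
    ll <- model$loglik
    n <- model$n
  } else {
    obs <- .as_obs(obs)
    eps <- model$control$eps
    t <- pmin(pmax(obs$t, eps), 1 - eps)
    sc <- pmin(pmax(obs$s, model$s_range[1L]), model$s_range[2L])
    B <- .basis_eval(model$basis, sc)
    ll <- sum(fam$loglik(t, B %*% model$coef))
    n <- nrow(obs)
  }
  edf <- sum(model$edf)
  list(aic = -2 * ll + 2 * edf, bic = -2 * ll + edf * log(n),
       edf = edf, loglik = ll, n = n)
}
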