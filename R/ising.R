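# Nearest-neighbour Ising representation of the methylation state within one
# genomic unit (GU), and the summary statistics computed from its level PMF.

#' Construct an Ising model for one genomic unit
#'
#' The methylation state of a GU with \code{L} CpG sites is the binary vector
#' \eqn{x = (x_1, ..., x_L)}, \eqn{x_n \in \{0,1\}}, with joint distribution
#' \deqn{\Pr[x] \propto \exp\{\sum_n a_n x_n + \sum_n b_n x_n x_{n+1}\},}
#' where \code{field} holds the per-site potentials \eqn{a_n} (controlling the
#' mean methylation of each site) and \code{coupling} the nearest-neighbour
#' potentials \eqn{b_n} (controlling correlation between adjacent sites).
#'
#' @param field Numeric vector of length \code{L >= 1}; per-site potentials.
#' @param coupling Numeric vector of length \code{L - 1}; nearest-neighbour
#'   potentials. Empty for \code{L = 1}.
#' @return An object of class \code{"ising_gu"}.
#' @seealso [level_pmf_from_ising()]
#' @export
#' @examples
#' gu <- ising_gu(field = c(0, 0), coupling = log(3))
#' level_pmf_from_ising(gu)$probs  # (1/6, 1/3, 1/2)
ising_gu <- function(field, coupling = numeric(0)) {
  field <- as.numeric(field)
  coupling <- as.numeric(coupling)
  L <- length(field)
  if (L < 1L) {
    stop("an Ising GU needs at least one CpG site")
  }
  if (length(coupling) != L - 1L) {
    stop("coupling must have length L - 1 = ", L - 1L,
         ", got ", length(coupling))
  }
  if (!all(is.finite(field)) || !all(is.finite(coupling))) {
    stop("Ising parameters must be finite")
  }
  structure(list(cpg_count = L, field = field, coupling = coupling),
            class = "ising_gu")
}

#' Construct a methylation-level PMF
#'
#' The methylation level of a GU with \code{L} CpG sites is
#' \eqn{M = (1/L)\sum_\ell X_\ell}, a random variable on the support
#' \eqn{\{0, 1/L, ..., 1\}}. This constructor validates and renormalizes a
#' probability vector over that support.
#'
#' @param probs Numeric vector of length \code{L + 1}, nonnegative, summing to
#'   1 within \code{1e-8} (renormalized exactly on construction).
#' @param cpg_count Number of CpG sites \code{L}; defaults to
#'   \code{length(probs) - 1}.
#' @return An object of class \code{"methylation_pmf"} with fields
#'   \code{cpg_count} and \code{probs}.
#' @export
methylation_pmf <- function(probs, cpg_count = length(probs) - 1L) {
  probs <- as.numeric(probs)
  L <- as.integer(cpg_count)
  if (L < 1L) stop("cpg_count must be >= 1")
  if (length(probs) != L + 1L) {
    stop("probs must have length L + 1 = ", L + 1L, ", got ", length(probs))
  }
  if (!all(is.finite(probs)) || any(probs < 0)) {
    stop("probabilities must be finite and nonnegative")
  }
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-8) {
    stop("probabilities must sum to 1 within 1e-8 (got ", format(tot), ")")
  }
  structure(list(cpg_count = L, probs = probs / tot),
            class = "methylation_pmf")
}

#' @export
print.methylation_pmf <- function(x, ...) {
  cat("methylation-level PMF over", x$cpg_count + 1L, "levels (L =",
      x$cpg_count, "CpG sites)\n")
  print(stats::setNames(round(x$probs, 4),
                        format(seq(0, 1, length.out = x$cpg_count + 1L),
                               digits = 3)))
  invisible(x)
}

# Exact level probabilities by a dynamic program over (site, running count,
# state of the current site). f[c + 1, x + 1] is the unnormalized weight of
# all configurations of the first n sites with methylated count c and
# x_n = x. Rescaled each step so large potentials cannot overflow.
.level_probs_ising <- function(field, coupling) {
  L <- length(field)
  f <- matrix(0, L + 1L, 2L)
  # per-site potentials are max-shifted before exponentiation (a common
  # factor per site cancels in the final normalization), so arbitrarily
  # large parameters neither overflow nor underflow
  m1 <- max(0, field[1L])
  f[1L, 1L] <- exp(-m1)
  f[2L, 2L] <- exp(field[1L] - m1)
  if (L > 1L) {
    for (n in 2L:L) {
      a <- field[n]
      ab <- field[n] + coupling[n - 1L]
      m <- max(0, a, ab)
      g <- matrix(0, L + 1L, 2L)
      g[, 1L] <- (f[, 1L] + f[, 2L]) * exp(-m)
      g[2L:(L + 1L), 2L] <- f[1L:L, 1L] * exp(a - m) + f[1L:L, 2L] * exp(ab - m)
      f <- g / max(g)
    }
  }
  p <- f[, 1L] + f[, 2L]
  p / sum(p)
}

#' Exact methylation-level PMF under the Ising model
#'
#' Computes the distribution of \eqn{M = (1/L)\sum_\ell X_\ell} exactly by a
#' dynamic program over (site index, running methylated count, current site
#' state), i.e. in \eqn{O(L^2)} instead of \eqn{O(2^L)} enumeration.
#'
#' @param gu An [ising_gu()] object.
#' @return A [methylation_pmf()] over \code{gu$cpg_count + 1} levels.
#' @export
level_pmf_from_ising <- function(gu) {
  if (!inherits(gu, "ising_gu")) stop("gu must be an 'ising_gu' object")
  methylation_pmf(.level_probs_ising(gu$field, gu$coupling), gu$cpg_count)
}

.pmf_probs <- function(pmf) {
  if (inherits(pmf, "methylation_pmf")) pmf$probs else as.numeric(pmf)
}

#' Mean methylation level (MML)
#'
#' \eqn{E[M] = \sum_m m \Pr[M = m]} over the support \eqn{\{0, 1/L, ..., 1\}}.
#'
#' @param pmf A [methylation_pmf()] object.
#' @return A number in \[0, 1\].
#' @export
mml <- function(pmf) {
  p <- .pmf_probs(pmf)
  L <- length(p) - 1L
  sum(seq(0, 1, length.out = L + 1L) * p)
}

#' Normalized methylation entropy (NME)
#'
#' Shannon entropy of the level PMF in bits, normalized by its maximum
#' \eqn{\log_2(L + 1)}: 1 for the uniform distribution over the \code{L + 1}
#' levels, 0 for a point mass. Uses the \eqn{0 \log 0 = 0} convention.
#'
#' @param pmf A [methylation_pmf()] object.
#' @return A number in \[0, 1\].
#' @export
nme <- function(pmf) {
  p <- .pmf_probs(pmf)
  L <- length(p) - 1L
  pp <- p[p > 0]
  h <- -sum(pp * log2(pp)) / log2(L + 1)
  min(max(h, 0), 1)
}
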