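# Jensen-Shannon distances, per-GU mutual information, and the feature-level
# test statistic T.

#' Jensen-Shannon distance between two methylation-level PMFs
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms,
#' \deqn{JSD^2 = \tfrac12 KL(p \| m) + \tfrac12 KL(q \| m), \quad m = (p+q)/2,}
#' a bounded metric on distributions: 0 iff \code{p == q}, 1 for disjoint
#' supports. Both PMFs must live on the same support (same number of CpG
#' sites); a mismatch signals an upstream error and is rejected.
#'
#' @param p,q [methylation_pmf()] objects (or bare probability vectors of
#'   equal length).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))  # ~0.5579
jsd <- function(p, q) {
  pp <- .pmf_probs(p)
  qq <- .pmf_probs(q)
  if (length(pp) != length(qq)) {
    stop("PMFs have mismatched supports (", length(pp) - 1L, " vs ",
         length(qq) - 1L, " CpG sites)")
  }
  m <- (pp + qq) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  d2 <- 0.5 * kl(pp) + 0.5 * kl(qq)
  sqrt(min(max(d2, 0), 1))
}

#' Feature-level test statistic T
#'
#' Root-mean-square of the per-GU Jensen-Shannon distances within a feature:
#' \deqn{T = \sqrt{(1/K) \sum_{k=1}^K JSD(k)^2}.}
#' T is 0 iff methylation carries no information about the phenotype in any
#' GU and 1 iff it is maximally informative in every GU; at uniform phenotype
#' prior, \eqn{T^2} equals the average per-GU mutual information. Unlike the
#' plain mean of squared JSDs, T satisfies the triangle inequality across
#' phenotypes, which makes it a proper discordance measure.
#'
#' @param jsds Numeric vector of per-GU JSD values in \[0, 1\] (\code{K >= 1}).
#' @return A number in \[0, 1\].
#' @export
t_statistic <- function(jsds) {
  jsds <- as.numeric(jsds)
  if (length(jsds) == 0L) stop("t_statistic needs at least one JSD value")
  if (any(!is.finite(jsds)) || any(jsds < 0) || any(jsds > 1)) {
    stop("JSD values must lie in [0, 1]")
  }
  sqrt(mean(jsds^2))
}

#' Mutual information between the methylation level of one GU and the phenotype
#'
#' \eqn{I(M_k; Q)} in bits, where the phenotype \eqn{Q} is 1 (test) with
#' probability \code{prior_test} and 0 (reference) otherwise, and
#' \eqn{\Pr[M_k | Q = 1]}, \eqn{\Pr[M_k | Q = 0]} are the test and reference
#' level PMFs. At \code{prior_test = 1/2} this equals
#' \code{jsd(p_test, p_ref)^2}.
#'
#' @param p_test,p_ref [methylation_pmf()] objects on the same support.
#' @param prior_test \eqn{\Pr[Q = 1]} in (0, 1); default 0.5.
#' @return Mutual information in bits (nonnegative).
#' @export
gu_mutual_information <- function(p_test, p_ref, prior_test = 0.5) {
  pt_ <- .pmf_probs(p_test)
  pr_ <- .pmf_probs(p_ref)
  if (length(pt_) != length(pr_)) {
    stop("PMFs have mismatched supports")
  }
  if (!is.finite(prior_test) || prior_test <= 0 || prior_test >= 1) {
    stop("prior_test must lie strictly in (0, 1)")
  }
  pq <- c(prior_test, 1 - prior_test)        # Pr[Q = 1], Pr[Q = 0]
  pm <- pq[1] * pt_ + pq[2] * pr_            # marginal Pr[M = m]
  term <- function(cond, prior) {
    joint <- prior * cond
    i <- joint > 0
    sum(joint[i] * log2(joint[i] / (pm[i] * prior)))
  }
  max(term(pt_, pq[1]) + term(pr_, pq[2]), 0)
}

#' Average mutual information over the GUs of a feature
#'
#' \eqn{(1/K) \sum_k I(M_k; Q)}; at uniform prior this equals
#' \code{t_statistic(jsds)^2} for the corresponding per-GU JSDs.
#'
#' @param gu_pairs List of length-\code{K} where each element is a list or
#'   pair \code{list(test = , ref = )} of [methylation_pmf()] objects (bare
#'   two-element lists are accepted positionally).
#' @param prior_test \eqn{\Pr[Q = 1]} in (0, 1).
#' @return Average mutual information in bits.
#' @export
average_mutual_information <- function(gu_pairs, prior_test = 0.5) {
  if (length(gu_pairs) == 0L) stop("gu_pairs must be non-empty")
  vals <- vapply(gu_pairs, function(pair) {
    gu_mutual_information(pair[[1L]], pair[[2L]], prior_test)
  }, numeric(1))
  mean(vals)
}
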