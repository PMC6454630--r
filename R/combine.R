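# Combining p-values: Fisher's statistic over promoter/body with an
# empirical null CDF (robust to the correlation between the two tests),
# Fisher's chi-squared combination across independent test/reference
# comparisons, rank products for tie-breaking, and BH q-values.

#' Fisher's summary statistic for a promoter/body pair
#'
#' \eqn{T_{pb} = -2 \ln P_p - 2 \ln P_b}. Under independence of the two
#' tests this is chi-squared with 4 df, but promoter and body methylation are
#' correlated, so significance should be taken from an empirical null
#' ([empirical_pb_pvalue()]) rather than the chi-squared distribution.
#'
#' @param p_p,p_b Promoter and body p-values in (0, 1\]; recycled.
#' @return The combined statistic (nonnegative). \code{NA} inputs give
#'   \code{NA} (such features are excluded from the combined list).
#' @export
fisher_pb <- function(p_p, p_b) {
  ok <- is.na(p_p) | is.na(p_b) |
    (p_p > 0 & p_p <= 1 & p_b > 0 & p_b <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]")
  -2 * log(p_p) - 2 * log(p_b)
}

#' Empirical null distribution of a combined statistic
#'
#' Stores sorted observations of \eqn{T_{pb}} pooled over all features and
#' all reference/reference comparison pairs, defining the empirical CDF
#' \eqn{\hat F_{pb}(t) = (1/N_r) \sum_n I[t_n \le t]}.
#'
#' @param values Numeric vector of null statistic observations (finite,
#'   nonnegative; \code{NA}s are dropped).
#' @return An object of class \code{"empirical_null"}.
#' @export
empirical_null <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empirical null needs at least one value")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("null statistic values must be finite and nonnegative")
  }
  structure(list(values = sort(values), n = length(values)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat("empirical null of the combined statistic:", x$n, "observations,",
      sprintf("range [%.3g, %.3g]\n", x$values[1L], x$values[x$n]))
  invisible(x)
}

#' p-value from the empirical null CDF
#'
#' \eqn{P \simeq 1 - \hat F_{pb}(t_*)}, clamped below at
#' \eqn{1/(N_r + 1)} — the resolution limit of an empirical CDF with
#' \eqn{N_r} observations — so downstream logarithms stay finite.
#'
#' @param t_star Observed combined statistic value(s).
#' @param null An [empirical_null()] object.
#' @return p-values in \eqn{[1/(N_r+1), 1]} (\code{NA} for \code{NA} input).
#' @export
empirical_pb_pvalue <- function(t_star, null) {
  if (!inherits(null, "empirical_null")) {
    stop("null must be an 'empirical_null' object")
  }
  cnt <- findInterval(t_star, null$values)
  p <- 1 - cnt / null$n
  p <- pmax(p, 1 / (null$n + 1))
  p[is.na(t_star)] <- NA_real_
  p
}

#' Upper-tail chi-squared p-value for Fisher's combined statistic
#'
#' @param t Statistic value(s), nonnegative.
#' @param df Degrees of freedom: a positive even integer (2 per combined
#'   p-value).
#' @return Upper-tail probabilities in (0, 1\].
#' @export
chi2_fisher_pvalue <- function(t, df) {
  if (length(df) != 1L || !is.finite(df) || df <= 0 || df %% 2 != 0) {
    stop("df must be a positive even integer")
  }
  if (any(t < 0)) stop("the combined statistic is nonnegative")
  pchisq(t, df = df, lower.tail = FALSE)
}

#' Fisher combination across multiple test/reference comparisons
#'
#' \eqn{T_{mult} = -2 \sum_{n=1}^{N_t} \ln P^{(n)}}, referred to the
#' chi-squared distribution with \eqn{2 N_t} degrees of freedom (the
#' comparisons use distinct samples and are treated as independent).
#' p-values of exactly 0 are clamped to \code{1e-300} before the logarithm.
#'
#' @param pvals Vector of per-comparison p-values in (0, 1\].
#' @return A list with \code{t_mult} and \code{p}.
#' @export
fisher_mult <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0L) stop("fisher_mult needs at least one p-value")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  t_mult <- -2 * sum(log(pmax(pvals, 1e-300)))
  list(t_mult = t_mult, p = chi2_fisher_pvalue(t_mult, 2L * length(pvals)))
}

#' Rank products across comparisons
#'
#' Geometric mean of a feature's ranks across comparisons; used only to
#' break ties in the combined ranking (numerically indistinguishable
#' combined p-values), not for significance testing.
#'
#' @param rank_matrix Features x comparisons matrix of ranks (ties as
#'   average ranks).
#' @return Numeric vector of rank products, one per feature.
#' @export
rank_products <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  if (any(!is.finite(rank_matrix)) || any(rank_matrix < 1)) {
    stop("ranks must be finite and >= 1")
  }
  exp(rowMeans(log(rank_matrix)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values with enforced monotonicity
#' (\code{stats::p.adjust}, method \code{"BH"}).
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\].
#' @export
bh_qvalues <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Assemble a ranked feature table from per-comparison p-values
#'
#' For one comparison the feature's combined p-value is its p-value; for
#' several, [fisher_mult()] is applied per feature. Features are ranked by
#' combined p-value ascending, ties broken by the rank product of the
#' per-comparison rankings, then by feature id; q-values come from
#' [bh_qvalues()] on the combined p-values.
#'
#' @param pmat Features x comparisons matrix (or data frame) of p-values;
#'   rownames (or \code{feature_ids}) identify features. Rows with any
#'   missing p-value are dropped with a message.
#' @param feature_ids Optional character vector of feature ids.
#' @return A \code{data.frame} sorted by final rank with columns
#'   \code{feature_id}, the per-comparison p-values, \code{t_mult},
#'   \code{p}, \code{rank_product}, \code{q}, \code{rank}.
#' @export
assemble_ranking <- function(pmat, feature_ids = rownames(pmat)) {
  pmat <- as.matrix(pmat)
  if (nrow(pmat) == 0L) stop("assemble_ranking needs at least one feature")
  if (is.null(feature_ids)) feature_ids <- as.character(seq_len(nrow(pmat)))
  storage.mode(pmat) <- "double"
  complete <- rowSums(is.na(pmat)) == 0L
  if (!all(complete)) {
    message(sum(!complete), " feature(s) dropped: missing p-value in at ",
            "least one comparison")
    pmat <- pmat[complete, , drop = FALSE]
    feature_ids <- feature_ids[complete]
  }
  if (nrow(pmat) == 0L) stop("no feature has a p-value in every comparison")
  nt <- ncol(pmat)
  comb <- t(apply(pmat, 1L, function(p) unlist(fisher_mult(p))))
  ranks <- apply(pmat, 2L, rank, ties.method = "average")
  ranks <- matrix(ranks, nrow = nrow(pmat))
  rp <- rank_products(ranks)
  q <- bh_qvalues(comb[, "p"])
  ord <- order(comb[, "p"], rp, feature_ids)
  out <- data.frame(feature_id = feature_ids, stringsAsFactors = FALSE)
  colnames(pmat) <- if (!is.null(colnames(pmat)) &&
                        !anyDuplicated(colnames(pmat))) {
    paste0("p_", colnames(pmat))
  } else {
    paste0("p_", seq_len(nt))
  }
  out <- cbind(out, as.data.frame(pmat, row.names = NULL))
  out$t_mult <- comb[, "t_mult"]
  out$p <- comb[, "p"]
  out$rank_product <- rp
  out$q <- q
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the empirical promoter/body null from reference/reference p-values
#'
#' Computes \eqn{T_{pb}} for every feature in every reference/reference
#' comparison pair and pools all values into one [empirical_null()].
#'
#' @param pp_mat,pb_mat Features x reference-pairs matrices of promoter and
#'   body p-values (aligned rows/columns). Entries missing either p-value
#'   are skipped.
#' @return An [empirical_null()] object.
#' @export
build_pb_null <- function(pp_mat, pb_mat) {
  pp_mat <- as.matrix(pp_mat)
  pb_mat <- as.matrix(pb_mat)
  if (!all(dim(pp_mat) == dim(pb_mat))) {
    stop("promoter and body p-value matrices must have identical shape")
  }
  vals <- fisher_pb(as.numeric(pp_mat), as.numeric(pb_mat))
  empirical_null(vals[!is.na(vals)])
}

#' Combined promoter/body p-values for one comparison
#'
#' @param p_p,p_b Promoter and body p-values per feature.
#' @param null The [empirical_null()] of \eqn{T_{pb}} from
#'   [build_pb_null()].
#' @return p-values (NA where either input is missing).
#' @export
pb_pvalues <- function(p_p, p_b, null) {
  empirical_pb_pvalue(fisher_pb(p_p, p_b), null)
}
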