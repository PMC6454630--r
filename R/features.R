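# Deriving promoter/body features from gene models, mapping data-bearing GUs
# to features, and scoring features with T and a p-value. All coordinates are
# 0-based half-open (BED/bedGraph native).

.check_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stop("gene models must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene models must have start < end")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

.tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' Derive promoter features from gene models
#'
#' The promoter of a gene is the window of \code{2 * half_width} bp centered
#' at its transcription start site (TSS = \code{start} on the + strand,
#' \code{end} on the - strand), floored at position 0.
#'
#' @param genes Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}.
#' @param half_width Promoter half-width in bp (default 2000, i.e. a 4-kb
#'   window).
#' @return Data frame of features: \code{feature_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{kind = "promoter"}, \code{strand}.
#' @export
derive_promoters <- function(genes, half_width = 2000L) {
  .check_gene_models(genes)
  tss <- .tss(genes)
  data.frame(feature_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(tss - half_width, 0L), end = tss + half_width,
             kind = "promoter", strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Derive gene-body features from gene models
#'
#' The gene body is the part of the gene interval (TSS to termination site)
#' that does not overlap the gene's promoter window. Genes entirely covered
#' by their promoter yield an empty sentinel interval (\code{start == end}),
#' which is never scored.
#'
#' @inheritParams derive_promoters
#' @return Data frame of features with \code{kind = "gene_body"}.
#' @export
derive_gene_bodies <- function(genes, half_width = 2000L) {
  .check_gene_models(genes)
  plus <- genes$strand == "+"
  # promoter straddles the TSS, so the remainder is a single interval on the
  # far side of the termination site
  start <- ifelse(plus, pmin(genes$start + half_width, genes$end), genes$start)
  end <- ifelse(plus, genes$end, pmax(genes$end - half_width, genes$start))
  data.frame(feature_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, kind = "gene_body",
             strand = genes$strand, stringsAsFactors = FALSE)
}

.check_features <- function(features) {
  need <- c("feature_id", "chrom", "start", "end")
  if (!is.data.frame(features) || !all(need %in% names(features))) {
    stop("features must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(features$start > features$end)) {
    stop("features must have start <= end (start == end marks an empty ",
         "sentinel)")
  }
  if (anyDuplicated(features$feature_id)) {
    stop("feature_id values must be unique within one feature set")
  }
  invisible(features)
}

.check_track <- function(track) {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    stop("a GU track must be a data frame with columns chrom, start, end ",
         "and a value column")
  }
  if (!"jsd" %in% names(track)) {
    vcol <- setdiff(names(track), need)[1L]
    if (is.na(vcol)) stop("track has no value column")
    track$jsd <- track[[vcol]]
  }
  track
}

#' Map data-bearing GUs to features
#'
#' A GU "has data" for a comparison iff a value is present in the track; a GU
#' counts toward a feature under \code{rule = "any"} when it overlaps the
#' feature by at least 1 bp, or under \code{rule = "midpoint"} when its
#' midpoint falls inside the feature.
#'
#' @param features Feature data frame (see [derive_promoters()]); a single
#'   row is accepted.
#' @param track Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{jsd}: the per-GU JSD values of one comparison
#'   (non-overlapping intervals).
#' @param rule Overlap rule, \code{"any"} (default) or \code{"midpoint"}.
#' @return A list with one element per feature row, each containing \code{K}
#'   (the GU count) and \code{jsds} (values in genomic order).
#' @export
assign_gus <- function(features, track, rule = c("any", "midpoint")) {
  rule <- match.arg(rule)
  .check_features(features)
  track <- .check_track(track)
  n <- nrow(features)
  out <- rep(list(list(K = 0L, jsds = numeric(0))), n)
  names(out) <- features$feature_id
  keep <- !is.na(track$jsd)
  track <- track[keep, , drop = FALSE]
  nonempty <- which(features$start < features$end)
  if (length(nonempty) == 0L || nrow(track) == 0L) return(out)

  fg <- GenomicRanges::GRanges(
    features$chrom[nonempty],
    IRanges::IRanges(features$start[nonempty] + 1L, features$end[nonempty]))
  if (rule == "midpoint") {
    mid <- (track$start + track$end) %/% 2L
    gg <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(mid + 1L,
                                                               mid + 1L))
  } else {
    gg <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L,
                                                  track$end))
  }
  # chromosomes present only on one side are legitimate (no overlap), so the
  # disjoint-seqlevels warning is noise here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(fg, gg))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    ord <- order(qh, track$start[sh])
    qh <- qh[ord]; sh <- sh[ord]
    for (i in unique(qh)) {
      idx <- sh[qh == i]
      out[[nonempty[i]]] <- list(K = length(idx), jsds = track$jsd[idx])
    }
  }
  out
}

#' Score one genomic feature
#'
#' Computes \code{K}, the size \eqn{s = \log_2 K}, the statistic
#' \code{t_stat = } [t_statistic()] over the feature's data-bearing GUs, and
#' (when a null model is supplied) the p-value [null_pvalue()]. Features with
#' no data (\code{K = 0}) are returned unscored (\code{NA} statistic).
#'
#' @param feature One-row feature data frame.
#' @param track Per-GU JSD track of one comparison.
#' @param model Optional fitted [fit_null_model()] object.
#' @param rule Overlap rule passed to [assign_gus()].
#' @return A one-row data frame \code{feature_id, K, s, t_stat, p}.
#' @export
score_feature <- function(feature, track, model = NULL, rule = "any") {
  score_features(feature, track, model = model, rule = rule)
}

#' Score a set of genomic features in one comparison
#'
#' @param features Feature data frame.
#' @param track Per-GU JSD track of one comparison.
#' @param model Optional fitted [fit_null_model()] object; without it the
#'   \code{p} column is \code{NA}.
#' @param rule Overlap rule passed to [assign_gus()].
#' @return Data frame with one row per feature: \code{feature_id},
#'   \code{kind} (if present), \code{K}, \code{s}, \code{t_stat}, \code{p}.
#'   Apply [size_filter()] to drop features with too little data.
#' @export
score_features <- function(features, track, model = NULL, rule = "any") {
  asg <- assign_gus(features, track, rule = rule)
  K <- vapply(asg, function(a) a$K, integer(1))
  t_stat <- vapply(asg, function(a) {
    if (a$K == 0L) NA_real_ else t_statistic(a$jsds)
  }, numeric(1))
  s <- ifelse(K > 0L, log2(pmax(K, 1L)), NA_real_)
  p <- rep(NA_real_, length(K))
  if (!is.null(model)) {
    i <- which(K > 0L)
    if (length(i)) p[i] <- null_pvalue(t_stat[i], s[i], model)
  }
  out <- data.frame(feature_id = features$feature_id, K = K, s = s,
                    t_stat = t_stat, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  if ("kind" %in% names(features)) out$kind <- features$kind
  out
}

#' Filter scored features by minimum GU count
#'
#' Retains features overlapping at least \code{k_min} data-bearing GUs
#' (\eqn{s \ge s_{min} = \log_2 K_{min}}), so that only features with
#' sufficient length and/or data enter the analysis. Typical choices:
#' 10 for gene bodies, 5 for shorter custom regions such as bivalent domains.
#'
#' @param scores Data frame from [score_features()].
#' @param k_min Minimum GU count, \code{>= 1}.
#' @return The retained rows of \code{scores}.
#' @export
size_filter <- function(scores, k_min) {
  if (!is.numeric(k_min) || k_min < 1) stop("k_min must be >= 1")
  scores[!is.na(scores$K) & scores$K >= k_min, , drop = FALSE]
}
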