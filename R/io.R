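# Readers/writers for the plain-text dialects the pipeline speaks: bedGraph
# tracks (chrom, start, end, value), BED features, gene-model TSVs, PMF
# tables, (t, s) observation TSVs, and the JSON null-model serialization.
# Coordinates are 0-based half-open throughout, preserved exactly.

.stop_line <- function(path, line, why) {
  stop(basename(path), " line ", line, ": ", why, call. = FALSE)
}

#' Read a per-GU value track (bedGraph)
#'
#' Four tab-separated columns, no header: chrom, start, end (0-based
#' half-open), value. GU intervals must not overlap within a chromosome.
#'
#' @param path File path.
#' @param value_range Optional length-2 numeric; values outside it are an
#'   error (JSD/MML/NME tracks use \code{c(0, 1)}).
#' @param value_name Name for the value column (default \code{"jsd"}).
#' @return Data frame \code{chrom, start, end, <value_name>}.
#' @export
read_track <- function(path, value_range = c(0, 1), value_name = "jsd") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  if (ncol(df) != 4L) stop(basename(path), ": expected 4 columns")
  names(df) <- c("chrom", "start", "end", value_name)
  bad <- which(df$start >= df$end)
  if (length(bad)) .stop_line(path, bad[1L], "start >= end")
  if (!is.null(value_range)) {
    v <- df[[value_name]]
    bad <- which(!is.finite(v) | v < value_range[1L] | v > value_range[2L])
    if (length(bad)) {
      .stop_line(path, bad[1L], paste0("value outside [",
                 value_range[1L], ", ", value_range[2L], "]"))
    }
  }
  ord <- order(df$chrom, df$start)
  sdf <- df[ord, ]
  ovl <- with(sdf, chrom[-1L] == chrom[-nrow(sdf)] &
                start[-1L] < end[-nrow(sdf)])
  if (nrow(df) > 1L && any(ovl)) {
    .stop_line(path, ord[which(ovl)[1L] + 1L], "overlapping GU intervals")
  }
  df
}

#' Write a per-GU value track (bedGraph)
#'
#' @param track Data frame \code{chrom, start, end, <value>}.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  write.table(track[, 1:4], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic features from BED
#'
#' BED3-BED6; column 4 (name) becomes \code{feature_id} (generated when
#' absent), column 6 the strand. Features get \code{kind = "custom"}.
#'
#' @param path File path.
#' @return Feature data frame (see [derive_promoters()] for the columns).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(basename(path), ": expected at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad)) .stop_line(path, bad[1L], "start >= end")
  out$feature_id <- if (ncol(df) >= 4L) {
    as.character(df[[4L]])
  } else {
    sprintf("feature%05d", seq_len(nrow(out)))
  }
  out$strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else "."
  out$kind <- "custom"
  out[, c("feature_id", "chrom", "start", "end", "kind", "strand")]
}

#' Write genomic features as BED6
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  strand <- if ("strand" %in% names(features)) features$strand else "."
  df <- data.frame(features$chrom, features$start, features$end,
                   features$feature_id, 0L, strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Tab-separated with header \code{gene_id, chrom, start, end, strand}
#' (0-based half-open; one row per gene model).
#'
#' @param path File path.
#' @return Validated gene-model data frame.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  .check_gene_models(df)
  bad <- which(df$start >= df$end)
  if (length(bad)) .stop_line(path, bad[1L] + 1L, "start >= end")
  df
}

#' Read / write per-GU methylation PMF tables
#'
#' Tab-separated, no header: chrom, start, end, L, then L + 1 probability
#' columns (rows may have different L; shorter rows are padded with empty
#' fields on disk).
#'
#' @param path File path.
#' @return A list with \code{gus} (data frame chrom, start, end, L) and
#'   \code{pmfs} (list of probability vectors).
#' @export
read_pmf_table <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts)
  gus <- data.frame(chrom = character(n), start = integer(n),
                    end = integer(n), L = integer(n),
                    stringsAsFactors = FALSE)
  pmfs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- parts[[i]]
    if (length(f) < 5L) .stop_line(path, i, "too few fields")
    L <- as.integer(f[4L])
    if (is.na(L) || length(f) != 4L + L + 1L) {
      .stop_line(path, i, "field count does not match L + 1 probabilities")
    }
    p <- as.numeric(f[5:(5L + L)])
    if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      .stop_line(path, i, "invalid probability vector")
    }
    gus$chrom[i] <- f[1L]
    gus$start[i] <- as.integer(f[2L])
    gus$end[i] <- as.integer(f[3L])
    gus$L[i] <- L
    pmfs[[i]] <- p / sum(p)
  }
  list(gus = gus, pmfs = pmfs)
}

#' @rdname read_pmf_table
#' @param gus Data frame \code{chrom, start, end, L}.
#' @param pmfs List of probability vectors (length \code{L + 1} each).
#' @export
write_pmf_table <- function(gus, pmfs, path) {
  stopifnot(nrow(gus) == length(pmfs))
  lines <- vapply(seq_len(nrow(gus)), function(i) {
    paste(c(gus$chrom[i], gus$start[i], gus$end[i], gus$L[i],
            format(pmfs[[i]], digits = 17, scientific = FALSE,
                   trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read (t, s) null observations
#'
#' Tab-separated with header columns \code{t} and \code{s}.
#'
#' @param path File path.
#' @return Data frame with columns \code{t}, \code{s}.
#' @export
read_observations <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  .as_obs(df)[, c("t", "s")]
}

#' @rdname read_observations
#' @param obs Data frame with columns \code{t}, \code{s}.
#' @export
write_observations <- function(obs, path) {
  write.table(.as_obs(obs)[, c("t", "s")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted null model
#'
#' Versioned JSON-text format holding the family, basis specification
#' (knots, boundary, degree), coefficient matrix, smoothing parameters,
#' training s-range and fit metadata. Round-trips exactly.
#'
#' @param model A fitted [fit_null_model()] object.
#' @param path Output path.
#' @export
write_null_model <- function(model, path) {
  if (!inherits(model, "methyl_null_model")) {
    stop("model must be a 'methyl_null_model'")
  }
  payload <- list(
    format = "methrank_null_model", version = 1L,
    family = model$family, par_names = model$par_names,
    basis = model$basis[c("type", "boundary", "knots", "degree", "ncol")],
    coef = as.numeric(model$coef), coef_dim = dim(model$coef),
    lambda = model$lambda, s_range = model$s_range, edf = model$edf,
    loglik = model$loglik, n = model$n, cycles = model$cycles,
    converged = model$converged,
    eps = model$control$eps)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "methrank_null_model")) {
    stop(basename(path), " is not a methrank null-model file")
  }
  basis <- list(type = x$basis$type, boundary = as.numeric(x$basis$boundary),
                knots = as.numeric(x$basis$knots),
                degree = as.integer(x$basis$degree),
                ncol = as.integer(x$basis$ncol))
  coef <- matrix(as.numeric(x$coef), nrow = x$coef_dim[1L],
                 ncol = x$coef_dim[2L])
  structure(list(family = x$family, par_names = x$par_names, basis = basis,
                 coef = coef, lambda = as.numeric(x$lambda),
                 s_range = as.numeric(x$s_range), edf = as.numeric(x$edf),
                 loglik = x$loglik, n = x$n, cycles = x$cycles,
                 converged = x$converged,
                 control = null_fit_control(eps = x$eps)),
            class = "methyl_null_model")
}

#' Write a ranked feature table
#'
#' @param table Data frame from [assemble_ranking()].
#' @param path Output path (TSV with header).
#' @export
write_ranked_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
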