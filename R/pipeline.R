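# End-to-end orchestration: fit the size-dependent null from
# reference/reference tracks, score features in every test/reference
# comparison, and assemble ranked lists (with promoter/body Fisher
# combination through the empirical null where gene models are supplied).

.clamp_p <- function(p) pmax(p, 1e-300)

#' Rank one feature set across test/reference comparisons
#'
#' Core in-memory pipeline for a single feature list: collect null (t, s)
#' observations by scoring the features in every reference/reference track,
#' fit (or reuse) the size-dependent null model, score every test/reference
#' track, and assemble the combined ranking (Fisher across comparisons when
#' there are several, rank-product tie-breaking, BH q-values).
#'
#' @param features Feature data frame (\code{feature_id, chrom, start, end}).
#' @param test_tracks Named list of per-GU JSD track data frames, one per
#'   test/reference comparison.
#' @param ref_tracks Named list of JSD tracks for the reference/reference
#'   comparisons (used to fit the null; may be \code{NULL} when \code{model}
#'   is supplied).
#' @param k_min Minimum data-bearing GU count for a feature to be scored.
#' @param model Optional pre-fitted [fit_null_model()] object.
#' @param control [null_fit_control()] for the fit.
#' @param rule Overlap rule passed to [assign_gus()].
#' @return A list with \code{model}, \code{null_obs}, \code{scores} (named
#'   list of per-comparison score frames), and \code{table} (the ranked
#'   table from [assemble_ranking()]).
#' @export
rank_features <- function(features, test_tracks, ref_tracks = NULL,
                          k_min = 5L, model = NULL,
                          control = null_fit_control(), rule = "any") {
  .check_features(features)
  if (!length(test_tracks)) stop("at least one test/reference track needed")
  if (is.null(names(test_tracks))) {
    names(test_tracks) <- paste0("comparison", seq_along(test_tracks))
  }
  null_obs <- NULL
  if (is.null(model)) {
    if (!length(ref_tracks)) {
      stop("no reference/reference input: supply ref_tracks or a fitted ",
           "model")
    }
    null_obs <- do.call(rbind, lapply(ref_tracks, function(tr) {
      sc <- size_filter(score_features(features, tr, rule = rule), k_min)
      data.frame(t = sc$t_stat, s = sc$s)
    }))
    model <- fit_null_model(null_obs, control)
  }
  scores <- lapply(test_tracks, function(tr) {
    size_filter(score_features(features, tr, model = model, rule = rule),
                k_min)
  })
  ids <- Reduce(intersect, lapply(scores, `[[`, "feature_id"))
  if (!length(ids)) stop("no feature passes the size filter in every ",
                         "comparison")
  pmat <- vapply(scores, function(sc) {
    .clamp_p(sc$p[match(ids, sc$feature_id)])
  }, numeric(length(ids)))
  pmat <- matrix(pmat, nrow = length(ids),
                 dimnames = list(ids, names(test_tracks)))
  list(model = model, null_obs = null_obs, scores = scores,
       table = assemble_ranking(pmat, feature_ids = ids))
}

#' Rank genes by promoter, body, and combined promoter/body discordance
#'
#' Derives promoter and gene-body features from gene models, fits one null
#' model per feature kind from the reference/reference tracks, and produces
#' three ranked lists: PR (promoters), GB (gene bodies), and PB — Fisher's
#' \eqn{T_{pb}} per gene referred to the empirical null pooled over all
#' genes and reference/reference pairs (promoter and body tests are
#' correlated, so the chi-squared null would be anticonservative). With
#' several test/reference comparisons each list is combined across them.
#'
#' @param gene_models Gene-model data frame (see [read_gene_models()]).
#' @param test_tracks,ref_tracks Named lists of per-GU JSD tracks.
#' @param half_width Promoter half-width in bp.
#' @param k_min_promoter,k_min_body Size filters per feature kind.
#' @param control [null_fit_control()] for the two null fits.
#' @param rule Overlap rule.
#' @return A list with \code{models} (per kind), \code{pb_null}, and
#'   \code{tables} (named list \code{pr}, \code{gb}, \code{pb} of ranked
#'   tables).
#' @export
rank_genes <- function(gene_models, test_tracks, ref_tracks,
                       half_width = 2000L, k_min_promoter = 1L,
                       k_min_body = 10L, control = null_fit_control(),
                       rule = "any") {
  .check_gene_models(gene_models)
  promoters <- derive_promoters(gene_models, half_width)
  bodies <- derive_gene_bodies(gene_models, half_width)
  if (is.null(names(test_tracks))) {
    names(test_tracks) <- paste0("comparison", seq_along(test_tracks))
  }

  fit_kind <- function(features, k_min) {
    obs <- do.call(rbind, lapply(ref_tracks, function(tr) {
      sc <- size_filter(score_features(features, tr, rule = rule), k_min)
      data.frame(t = sc$t_stat, s = sc$s)
    }))
    fit_null_model(obs, control)
  }
  m_pr <- fit_kind(promoters, k_min_promoter)
  m_gb <- fit_kind(bodies, k_min_body)

  pvec <- function(features, tr, model, k_min) {
    sc <- size_filter(score_features(features, tr, model = model,
                                     rule = rule), k_min)
    stats::setNames(.clamp_p(sc$p), sc$feature_id)
  }
  gene_ids <- gene_models$gene_id
  align <- function(v) v[match(gene_ids, names(v))]

  # per-comparison promoter and body p-values, aligned on the gene universe
  pp_test <- vapply(test_tracks, function(tr) {
    align(pvec(promoters, tr, m_pr, k_min_promoter))
  }, numeric(length(gene_ids)))
  pb_test <- vapply(test_tracks, function(tr) {
    align(pvec(bodies, tr, m_gb, k_min_body))
  }, numeric(length(gene_ids)))
  pp_test <- matrix(pp_test, nrow = length(gene_ids),
                    dimnames = list(gene_ids, names(test_tracks)))
  pb_test <- matrix(pb_test, nrow = length(gene_ids),
                    dimnames = list(gene_ids, names(test_tracks)))

  # empirical T_pb null pooled over genes and reference/reference pairs
  pp_ref <- vapply(ref_tracks, function(tr) {
    align(pvec(promoters, tr, m_pr, k_min_promoter))
  }, numeric(length(gene_ids)))
  pb_ref <- vapply(ref_tracks, function(tr) {
    align(pvec(bodies, tr, m_gb, k_min_body))
  }, numeric(length(gene_ids)))
  nullpb <- build_pb_null(pp_ref, pb_ref)

  ppb_test <- apply(rbind(pp_test, pb_test), 2L, function(col) {
    k <- length(gene_ids)
    pb_pvalues(col[seq_len(k)], col[k + seq_len(k)], nullpb)
  })
  ppb_test <- matrix(ppb_test, nrow = length(gene_ids),
                     dimnames = list(gene_ids, names(test_tracks)))

  tables <- list(pr = assemble_ranking(pp_test, gene_ids),
                 gb = assemble_ranking(pb_test, gene_ids),
                 pb = assemble_ranking(ppb_test, gene_ids))
  list(models = list(promoter = m_pr, gene_body = m_gb),
       pb_null = nullpb, tables = tables)
}

.read_maybe <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

.fit_diagnostics <- function(model, obs,
                             alphas = c(5, 25, 50, 75, 95)) {
  g <- quantile_residuals(obs, model)
  mom <- .moments(g)
  cov <- vapply(alphas, centile_coverage, numeric(1), obs = obs,
                model = model)
  data.frame(metric = c("n", "resid_mean", "resid_sd", "resid_skewness",
                        "resid_kurtosis",
                        paste0("coverage_", alphas)),
             value = c(nrow(obs), mom, cov))
}

.moments <- function(x) {
  m <- mean(x)
  s <- sd(x)
  z <- (x - m) / s
  c(mean = m, sd = s, skewness = mean(z^3), kurtosis = mean(z^4))
}

#' Run the file-based end-to-end pipeline
#'
#' Reads per-comparison JSD tracks and a feature definition (a BED file of
#' custom features, or gene models from which promoters and bodies are
#' derived), fits the size-dependent null(s) from the reference/reference
#' tracks, scores and ranks features in the test/reference comparisons, and
#' writes ranked TSVs, serialized null model(s), and a goodness-of-fit
#' diagnostics table to \code{out_dir}. Partial outputs are removed if any
#' stage fails. All stages are deterministic for identical inputs.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \code{test_tracks} (named character vector/list of bedGraph paths),
#'   \code{ref_tracks} (idem), exactly one of \code{features} (BED path) or
#'   \code{gene_models} (TSV path), \code{out_dir}, and optionally
#'   \code{k_min} (default 5), \code{k_min_promoter} (1), \code{k_min_body}
#'   (10), \code{half_width} (2000), \code{rule} ("any"), and named
#'   [null_fit_control()] entries under \code{fit}.
#' @return Invisibly, the result list of [rank_features()] or
#'   [rank_genes()], with \code{$out_files} naming everything written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  need <- c("test_tracks", "ref_tracks", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config is missing: ", paste(missing, collapse = ", "))
  }
  if (is.null(config$features) == is.null(config$gene_models)) {
    stop("config must name exactly one of 'features' (BED) or ",
         "'gene_models' (TSV)")
  }
  if (!length(config$ref_tracks)) {
    stop("no reference/reference input: the null model must be fitted ",
         "from ref_tracks")
  }
  fit_args <- config$fit
  control <- do.call(null_fit_control, if (is.null(fit_args)) list()
                     else fit_args)
  rule <- if (is.null(config$rule)) "any" else config$rule
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  read_tracks <- function(x) {
    paths <- as.list(x)
    if (is.null(names(paths)) || any(names(paths) == "")) {
      names(paths) <- vapply(paths, function(p) {
        if (is.character(p)) sub("\\.[^.]*$", "", basename(p)) else ""
      }, character(1))
    }
    lapply(paths, .read_maybe, reader = read_track)
  }

  written <- character(0)
  emit <- function(obj, file, writer) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }

  result <- tryCatch({
    test_tracks <- read_tracks(config$test_tracks)
    ref_tracks <- read_tracks(config$ref_tracks)
    message("methrank: ", length(test_tracks), " test/reference and ",
            length(ref_tracks), " reference/reference tracks")

    if (!is.null(config$features)) {
      features <- .read_maybe(config$features, read_bed)
      k_min <- if (is.null(config$k_min)) 5L else config$k_min
      message("methrank: ", nrow(features), " features read; size filter ",
              "K >= ", k_min)
      res <- rank_features(features, test_tracks, ref_tracks,
                           k_min = k_min, control = control, rule = rule)
      n_scored <- nrow(res$table)
      message("methrank: ", n_scored, " features scored in every ",
              "comparison, ", nrow(features) - n_scored,
              " unscored or filtered")
      emit(res$table, "ranked.tsv", write_ranked_table)
      emit(res$model, "null_model.json", write_null_model)
      emit(.fit_diagnostics(res$model, res$null_obs), "diagnostics.tsv",
           function(obj, path) write.table(obj, path, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE))
      res
    } else {
      genes <- .read_maybe(config$gene_models, read_gene_models)
      message("methrank: ", nrow(genes), " gene models read")
      res <- rank_genes(
        genes, test_tracks, ref_tracks,
        half_width = if (is.null(config$half_width)) 2000L
                     else config$half_width,
        k_min_promoter = if (is.null(config$k_min_promoter)) 1L
                         else config$k_min_promoter,
        k_min_body = if (is.null(config$k_min_body)) 10L
                     else config$k_min_body,
        control = control, rule = rule)
      for (nm in names(res$tables)) {
        message("methrank: ", nm, " list has ", nrow(res$tables[[nm]]),
                " genes")
        emit(res$tables[[nm]], paste0(nm, ".tsv"), write_ranked_table)
      }
      emit(res$models$promoter, "null_model_promoter.json",
           write_null_model)
      emit(res$models$gene_body, "null_model_gene_body.json",
           write_null_model)
      res
    }
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  result$out_files <- written
  invisible(result)
}
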