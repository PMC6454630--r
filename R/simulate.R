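# Synthetic replicate methylome cohorts with known ground truth, generated
# from the nearest-neighbour Ising forward model, plus direct (t, s) draws
# from a known logitSST parameter surface. Everything is deterministic given
# the configured seed.

#' Configuration of a synthetic cohort
#'
#' The generator emulates the design of a replicate reference study:
#' \code{n_ref} reference replicates share per-GU base Ising parameters and
#' differ by i.i.d. Gaussian field perturbations (biological/technical
#' variability); \code{n_test} test samples are generated the same way, but
#' inside planted features their fields are shifted by \code{-effect_size}
#' (hypomethylation) and their couplings multiplied by
#' \code{coupling_factor} (< 1 weakens correlation, raising methylation
#' entropy) — qualitatively mirroring hypomethylation-with-entropy-gain
#' presets. Consecutive GUs are tiled into features separated by one-GU
#' gaps.
#'
#' @param n_chroms Number of chromosomes.
#' @param gus_per_chrom GUs per chromosome.
#' @param gu_width GU width in bp (150 by default, the analysis resolution).
#' @param cpgs_per_gu Integer range \code{c(lo, hi)} of CpG sites per GU.
#' @param n_ref Number of reference replicates (default 4, a typical
#'   replicate reference cohort).
#' @param n_test Number of test samples.
#' @param replicate_noise_sd SD of the per-GU, per-sample field perturbation.
#' @param planted_fraction Fraction of features given a planted effect in
#'   test samples, in \[0, 1\].
#' @param effect_size Field shift applied inside planted features (toward
#'   unmethylated for positive values).
#' @param coupling_factor Multiplier on couplings inside planted features.
#' @param feature_gus Integer range of GUs per feature.
#' @param missing_fraction Fraction of GUs masked (no data) per sample.
#' @param base_field_mix Means, SDs and weights of the two-component base
#'   field mixture (methylated-leaning and unmethylated-leaning GUs).
#' @param site_field_sd Per-site jitter of the base field within a GU.
#' @param coupling_mean,coupling_sd Base coupling distribution.
#' @param seed Integer seed; same seed, same cohort.
#' @return A validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_chroms = 2L, gus_per_chrom = 1000L,
                          gu_width = 150L, cpgs_per_gu = c(2L, 8L),
                          n_ref = 4L, n_test = 3L,
                          replicate_noise_sd = 0.3,
                          planted_fraction = 0.1, effect_size = 3,
                          coupling_factor = 0.25,
                          feature_gus = c(5L, 15L),
                          missing_fraction = 0.02,
                          base_field_mix = list(means = c(2, -2),
                                                sds = c(1, 1),
                                                weights = c(0.7, 0.3)),
                          site_field_sd = 0.3, coupling_mean = 1,
                          coupling_sd = 0.5, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              gus_per_chrom = as.integer(gus_per_chrom),
              gu_width = as.integer(gu_width),
              cpgs_per_gu = as.integer(cpgs_per_gu),
              n_ref = as.integer(n_ref), n_test = as.integer(n_test),
              replicate_noise_sd = replicate_noise_sd,
              planted_fraction = planted_fraction,
              effect_size = effect_size,
              coupling_factor = coupling_factor,
              feature_gus = as.integer(feature_gus),
              missing_fraction = missing_fraction,
              base_field_mix = base_field_mix,
              site_field_sd = site_field_sd,
              coupling_mean = coupling_mean, coupling_sd = coupling_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chroms >= 1, gus_per_chrom >= 1, gu_width >= 1,
              length(cpgs_per_gu) == 2, cpgs_per_gu[1] >= 1,
              cpgs_per_gu[2] >= cpgs_per_gu[1],
              n_ref >= 2, n_test >= 1,
              replicate_noise_sd >= 0,
              planted_fraction >= 0, planted_fraction <= 1,
              length(feature_gus) == 2, feature_gus[1] >= 1,
              feature_gus[2] >= feature_gus[1],
              missing_fraction >= 0, missing_fraction < 1,
              site_field_sd >= 0, coupling_sd >= 0)
  })
  structure(cfg, class = "cohort_config")
}

.jsd_fast <- function(p, q) {
  m <- (p + q) / 2
  i <- p > 0
  j <- q > 0
  d2 <- 0.5 * sum(p[i] * log2(p[i] / m[i])) +
    0.5 * sum(q[j] * log2(q[j] / m[j]))
  sqrt(min(max(d2, 0), 1))
}

#' Simulate a replicate cohort with planted discordant features
#'
#' Generates per-sample methylation-level PMFs for every GU from the Ising
#' forward model, per-sample MML/NME tracks, per-comparison JSD tracks for
#' all reference/reference pairs and for each test sample paired with one
#' reference, and a feature table with ground-truth planted labels. Masked
#' GUs (missing data) are absent from any comparison involving that sample.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class \code{"methyl_cohort"}: \code{gus} (GU intervals
#'   with CpG counts), \code{features} (with logical \code{planted}),
#'   \code{pmfs} (per sample, list of level-probability vectors or NULL when
#'   masked), \code{mml}/\code{nme} (per-sample tracks),
#'   \code{ref_comparisons} and \code{test_comparisons} (named lists of JSD
#'   track data frames), and the \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be built with cohort_config()")
  }
  set.seed(config$seed)
  n_gus <- config$n_chroms * config$gus_per_chrom
  chrom <- rep(paste0("chr", seq_len(config$n_chroms)),
               each = config$gus_per_chrom)
  start <- rep((seq_len(config$gus_per_chrom) - 1L) * config$gu_width,
               config$n_chroms)
  L <- sample(config$cpgs_per_gu[1L]:config$cpgs_per_gu[2L], n_gus,
              replace = TRUE)
  gus <- data.frame(chrom = chrom, start = start,
                    end = start + config$gu_width, L = L,
                    stringsAsFactors = FALSE)

  # per-GU base parameters: bimodal field mixture, positive-leaning couplings
  mix <- config$base_field_mix
  comp <- sample(seq_along(mix$weights), n_gus, replace = TRUE,
                 prob = mix$weights)
  gu_mean <- rnorm(n_gus, mix$means[comp], mix$sds[comp])
  base_field <- lapply(seq_len(n_gus), function(i) {
    gu_mean[i] + rnorm(L[i], 0, config$site_field_sd)
  })
  base_coupling <- lapply(seq_len(n_gus), function(i) {
    if (L[i] > 1L) rnorm(L[i] - 1L, config$coupling_mean, config$coupling_sd)
    else numeric(0)
  })

  # tile consecutive GUs into features separated by a one-GU gap
  features <- local({
    rows <- list()
    fid <- 0L
    for (ch in seq_len(config$n_chroms)) {
      i <- 1L
      while (i <= config$gus_per_chrom) {
        len <- sample(config$feature_gus[1L]:config$feature_gus[2L], 1L)
        j <- min(i + len - 1L, config$gus_per_chrom)
        fid <- fid + 1L
        rows[[fid]] <- data.frame(
          feature_id = sprintf("feat%05d", fid),
          chrom = paste0("chr", ch),
          start = (i - 1L) * config$gu_width,
          end = j * config$gu_width,
          kind = "custom", stringsAsFactors = FALSE)
        i <- j + 2L
      }
    }
    do.call(rbind, rows)
  })
  n_feat <- nrow(features)
  n_planted <- round(config$planted_fraction * n_feat)
  features$planted <- FALSE
  if (n_planted > 0L) {
    features$planted[sample.int(n_feat, n_planted)] <- TRUE
  }

  # GU index -> planted feature membership
  planted_gu <- rep(FALSE, n_gus)
  if (n_planted > 0L) {
    pf <- features[features$planted, , drop = FALSE]
    for (r in seq_len(nrow(pf))) {
      ci <- match(pf$chrom[r], paste0("chr", seq_len(config$n_chroms)))
      lo <- pf$start[r] %/% config$gu_width + 1L
      hi <- pf$end[r] %/% config$gu_width
      planted_gu[(ci - 1L) * config$gus_per_chrom + (lo:hi)] <- TRUE
    }
  }

  sample_names <- c(paste0("ref", seq_len(config$n_ref)),
                    paste0("test", seq_len(config$n_test)))
  is_test <- grepl("^test", sample_names)
  pmfs <- vector("list", length(sample_names))
  names(pmfs) <- sample_names
  for (smp in seq_along(sample_names)) {
    masked <- runif(n_gus) < config$missing_fraction
    plist <- vector("list", n_gus)
    for (i in seq_len(n_gus)) {
      if (masked[i]) next
      a <- base_field[[i]] + rnorm(L[i], 0, config$replicate_noise_sd)
      b <- base_coupling[[i]]
      if (is_test[smp] && planted_gu[i]) {
        a <- a - config$effect_size
        b <- b * config$coupling_factor
      }
      plist[[i]] <- .level_probs_ising(a, b)
    }
    pmfs[[smp]] <- plist
  }

  track_of <- function(vals) {
    keep <- !is.na(vals)
    data.frame(chrom = gus$chrom[keep], start = gus$start[keep],
               end = gus$end[keep], jsd = vals[keep],
               stringsAsFactors = FALSE)
  }
  summaries <- function(fun) {
    lapply(pmfs, function(pl) {
      v <- vapply(pl, function(p) if (is.null(p)) NA_real_ else fun(p),
                  numeric(1))
      tr <- track_of(v)
      names(tr)[4L] <- "value"
      tr
    })
  }
  mml_tracks <- summaries(function(p) sum(seq(0, 1,
                                              length.out = length(p)) * p))
  nme_tracks <- summaries(function(p) {
    pp <- p[p > 0]
    -sum(pp * log2(pp)) / log2(length(p))
  })

  compare <- function(a, b) {
    va <- pmfs[[a]]
    vb <- pmfs[[b]]
    v <- rep(NA_real_, n_gus)
    for (i in seq_len(n_gus)) {
      if (!is.null(va[[i]]) && !is.null(vb[[i]])) {
        v[i] <- .jsd_fast(va[[i]], vb[[i]])
      }
    }
    track_of(v)
  }
  ref_comparisons <- list()
  for (a in seq_len(config$n_ref - 1L)) {
    for (b in (a + 1L):config$n_ref) {
      ref_comparisons[[paste0("ref", a, "_vs_ref", b)]] <-
        compare(paste0("ref", a), paste0("ref", b))
    }
  }
  test_comparisons <- list()
  for (k in seq_len(config$n_test)) {
    r <- (k - 1L) %% config$n_ref + 1L
    test_comparisons[[paste0("test", k, "_vs_ref", r)]] <-
      compare(paste0("test", k), paste0("ref", r))
  }

  structure(list(gus = gus, features = features, pmfs = pmfs,
                 mml = mml_tracks, nme = nme_tracks,
                 ref_comparisons = ref_comparisons,
                 test_comparisons = test_comparisons,
                 config = config), class = "methyl_cohort")
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic methylome cohort: %d GUs, %d features ",
                     "(%d planted), %d ref + %d test samples\n"),
              nrow(x$gus), nrow(x$features), sum(x$features$planted),
              x$config$n_ref, x$config$n_test))
  invisible(x)
}

#' Draw (t, s) observations from a known logitSST surface
#'
#' Sizes are uniform over \code{s_range}; each t is a logitSST draw at the
#' surface's parameters for its size. Used to exercise and validate the null
#' model fitter against a known truth.
#'
#' @param surface A list with functions (or constants) \code{mu},
#'   \code{sigma}, \code{nu}, \code{tau} of s.
#' @param n Number of observations.
#' @param s_range Length-2 numeric range of sizes.
#' @param seed Integer seed.
#' @return Data frame with columns \code{t} and \code{s}.
#' @export
simulate_null_observations <- function(surface, n, s_range = c(3, 10),
                                       seed = 1L) {
  need <- c("mu", "sigma", "nu", "tau")
  if (!is.list(surface) || !all(need %in% names(surface))) {
    stop("surface must be a list with elements mu, sigma, nu, tau")
  }
  evalp <- function(f, s) {
    if (is.function(f)) rep_len(f(s), length(s)) else rep_len(f, length(s))
  }
  stopifnot(length(s_range) == 2, s_range[2] >= s_range[1], n >= 1)
  set.seed(as.integer(seed))
  s <- runif(n, s_range[1L], s_range[2L])
  mu <- evalp(surface$mu, s)
  sigma <- evalp(surface$sigma, s)
  nu <- evalp(surface$nu, s)
  tau <- evalp(surface$tau, s)
  .check_sst_params(mu, sigma, nu, tau)
  data.frame(t = qlogitsst(runif(n), mu, sigma, nu, tau), s = s)
}
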