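# Shared fixture builders: everything is generated in code, nothing on disk.

# random PMF over L + 1 levels (Dirichlet-ish via normalized gammas)
random_pmf <- function(L, alpha = 1) {
  w <- rgamma(L + 1, shape = alpha)
  methylation_pmf(w / sum(w), L)
}

random_ising <- function(L, field_sd = 1.5, coupling_sd = 1) {
  ising_gu(rnorm(L, 0, field_sd),
           if (L > 1) rnorm(L - 1, 0, coupling_sd) else numeric(0))
}

# brute-force level PMF by enumerating all 2^L methylation configurations
enumerate_level_pmf <- function(gu) {
  L <- gu$cpg_count
  cfg <- as.matrix(expand.grid(rep(list(0:1), L)))
  inter <- if (L > 1) {
    apply(cfg, 1, function(x) sum(gu$coupling * x[-L] * x[-1]))
  } else 0
  w <- exp(drop(cfg %*% gu$field) + inter)
  p <- tapply(w, factor(rowSums(cfg), levels = 0:L), sum)
  p[is.na(p)] <- 0
  as.numeric(p) / sum(w)
}

# direct evaluation of Eq.-style mutual information as an independent oracle
mi_oracle <- function(p_test, p_ref, prior) {
  pt_ <- p_test$probs; pr_ <- p_ref$probs
  pm <- prior * pt_ + (1 - prior) * pr_
  tot <- 0
  for (q in c(1, 0)) {
    cond <- if (q == 1) pt_ else pr_
    pq <- if (q == 1) prior else 1 - prior
    for (m in seq_along(pm)) {
      joint <- pq * cond[m]
      if (joint > 0) tot <- tot + joint * log2(joint / (pm[m] * pq))
    }
  }
  tot
}

# a small GU track on a 150-bp grid with given values (NA = no data)
grid_track <- function(values, chrom = "chr1", width = 150L) {
  n <- length(values)
  df <- data.frame(chrom = chrom, start = (seq_len(n) - 1L) * width,
                   end = seq_len(n) * width, jsd = values,
                   stringsAsFactors = FALSE)
  df[!is.na(df$jsd), , drop = FALSE]
}

feature_row <- function(id, start, end, chrom = "chr1", kind = "custom") {
  data.frame(feature_id = id, chrom = chrom, start = start, end = end,
             kind = kind, stringsAsFactors = FALSE)
}

# a small fitted null model shared across tests (cached per session)
small_null_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      obs <- simulate_null_observations(
        list(mu = -2, sigma = 0.6, nu = 1.2, tau = 6),
        n = 2000, s_range = c(2, 6), seed = 42)
      cache <<- fit_null_model(obs, null_fit_control(
        n_knots = 8, lambda = 100, select_lambda = FALSE))
    }
    cache
  }
})
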