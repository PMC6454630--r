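genes <- data.frame(
  gene_id = c("gplus", "gminus", "gedge", "gsmall"),
  chrom = "chr1",
  start = c(10000L, 10000L, 1000L, 10000L),
  end = c(20000L, 20000L, 5000L, 11000L),
  strand = c("+", "-", "+", "+"),
  stringsAsFactors = FALSE)

test_that("promoters are 4-kb windows centered at the strand-aware TSS", {
  pr <- derive_promoters(genes)
  expect_equal(pr[pr$feature_id == "gplus", c("start", "end")],
               data.frame(start = 8000L, end = 12000L), ignore_attr = TRUE)
  expect_equal(pr[pr$feature_id == "gminus", c("start", "end")],
               data.frame(start = 18000L, end = 22000L), ignore_attr = TRUE)
  # floored at the chromosome start
  expect_equal(pr[pr$feature_id == "gedge", c("start", "end")],
               data.frame(start = 0L, end = 3000L), ignore_attr = TRUE)
  # width is exactly 2 * half_width away from the boundary
  expect_true(all((pr$end - pr$start)[pr$feature_id != "gedge"] == 4000L))
})

test_that("gene bodies are the gene minus its promoter", {
  gb <- derive_gene_bodies(genes)
  expect_equal(gb[gb$feature_id == "gplus", c("start", "end")],
               data.frame(start = 12000L, end = 20000L), ignore_attr = TRUE)
  expect_equal(gb[gb$feature_id == "gminus", c("start", "end")],
               data.frame(start = 10000L, end = 18000L), ignore_attr = TRUE)
  # a gene inside its promoter window leaves an empty sentinel body
  row <- gb[gb$feature_id == "gsmall", ]
  expect_equal(row$start, row$end)
})

test_that("promoter and body of a gene never overlap", {
  set.seed(41)
  rg <- data.frame(gene_id = sprintf("g%03d", 1:50), chrom = "chr2",
                   start = sort(sample.int(1e6, 50)), strand =
                     sample(c("+", "-"), 50, replace = TRUE),
                   stringsAsFactors = FALSE)
  rg$end <- rg$start + sample(500:20000, 50)
  pr <- derive_promoters(rg)
  gb <- derive_gene_bodies(rg)
  overlap <- pmin(pr$end, gb$end) - pmax(pr$start, gb$start)
  expect_true(all(overlap[gb$end > gb$start] <= 0))
})

test_that("GU assignment follows the >= 1 bp overlap rule", {
  track <- grid_track(c(0.1, 0.2, 0.3, 0.4))
  a <- assign_gus(feature_row("f", 300, 600), track)[[1]]
  expect_equal(a$K, 2L)
  expect_equal(a$jsds, c(0.3, 0.4))
  # a 20-bp feature straddling a GU boundary touches both GUs
  b <- assign_gus(feature_row("f", 290, 310), track)[[1]]
  expect_equal(b$K, 2L)
  expect_equal(b$jsds, c(0.2, 0.3))
  # under the midpoint rule it touches neither
  c_ <- assign_gus(feature_row("f", 290, 310), track, rule = "midpoint")[[1]]
  expect_equal(c_$K, 0L)
})

test_that("GUs without data and other chromosomes never count", {
  track <- grid_track(c(0.1, NA, 0.3))
  a <- assign_gus(feature_row("f", 0, 450), track)[[1]]
  expect_equal(a$K, 2L)
  expect_equal(a$jsds, c(0.1, 0.3))
  b <- assign_gus(feature_row("f", 0, 450, chrom = "chr9"), track)[[1]]
  expect_equal(b$K, 0L)
  expect_equal(b$jsds, numeric(0))
})

test_that("scoring computes K, s = log2 K, T, and p against the null", {
  m <- small_null_model()
  track <- grid_track(rep(0.2, 10))
  sc <- score_features(feature_row("f", 0, 1500), track, model = m)
  expect_equal(sc$K, 10L)
  expect_equal(sc$s, log2(10))
  expect_equal(sc$t_stat, 0.2)
  expect_equal(sc$p, null_pvalue(0.2, log2(10), m))
  # a feature with no data is unscored
  far <- score_features(feature_row("f", 1e6, 1e6 + 100), track, model = m)
  expect_equal(far$K, 0L)
  expect_true(is.na(far$t_stat) && is.na(far$p))
})

test_that("scoring is invariant to GU record order", {
  set.seed(42)
  track <- grid_track(runif(30))
  shuffled <- track[sample.int(nrow(track)), ]
  f <- feature_row(c("a", "b"), c(0, 2000), c(1800, 4500))
  expect_equal(score_features(f, shuffled), score_features(f, track))
})

test_that("the size filter keeps features with K >= k_min", {
  sc <- data.frame(feature_id = letters[1:5], K = c(8L, 9L, 10L, 11L, 12L),
                   s = log2(c(8, 9, 10, 11, 12)))
  kept <- size_filter(sc, 10)
  expect_equal(nrow(kept), 3L)
  expect_equal(min(kept$K), 10L)
  expect_equal(size_filter(sc, 1), sc)
  expect_equal(nrow(size_filter(data.frame(K = c(4L, 5L, 6L)), 5)), 2L)
  expect_error(size_filter(sc, 0), "k_min")
})
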