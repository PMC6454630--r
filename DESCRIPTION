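Package: methrank
Title: Ranking Genomic Features by DNA Methylation Discordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Information-theoretic scoring and ranking of genomic features
    (promoters, gene bodies, or any user-supplied regions) by DNA methylation
    discordance between a test and a reference phenotype. Per-genomic-unit
    methylation-level distributions are compared with the Jensen-Shannon
    distance, summarized into a mutual-information-derived test statistic, and
    assessed against a feature-size-dependent null model fitted to
    reference/reference comparisons by penalized-spline distributional
    regression with a logit skew-t family. Single- and multi-comparison
    rankings are obtained by Fisher combination with an empirical null,
    rank-product tie-breaking, and Benjamini-Hochberg q-values. Includes a
    nearest-neighbour Ising simulator of replicate methylomes with planted
    discordant features for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
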