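Package: nacnorm
Title: Normative Alpha-Centrality Analysis of Resting-State Functional
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds thresholded region-level functional connectivity graphs
    from resting-state BOLD time series, computes normalized alpha-centrality
    at alpha = 0 (degree-like, nAC0) and alpha = 1/lambda (eigenvector-like,
    nAC1) for every brain region, and flags per-subject abnormal regions
    against an age- and sex-resolved normative model fit on healthy controls
    (mean + 2 SD). Includes the correlation-significance machinery for
    autocorrelated time series (effective sample size, r to t to Z), motion
    quality control, band-pass filtering, downstream statistics (distribution
    chi-square, Wilcoxon rank-sum, Spearman and partial Spearman, Cohen's
    kappa, default-mode-network enrichment, edge-count ANCOVA), and a
    synthetic-cohort generator with community-structured covariance, AR(1)
    temporal autocorrelation, smooth age trends, and injectable hub
    abnormalities so the whole pipeline is testable without patient MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
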