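Package: dynfc
Title: Sliding-Window Dynamic Functional Connectivity and Mean-Variance
    Edge Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-varying (dynamic) functional
    connectivity from region-of-interest signal time-series. Computes
    edge-wise sliding-window correlation time-series (Spearman or
    Pearson), per-edge temporal mean and variance summaries with
    group averaging, a rank-correlation test of mean-variance scaling
    (Taylor's law), magnitude-based and variance-based edge
    binarization, and within- versus between-network variance
    contrasts. Includes a synthetic cohort generator with analytically
    known time-varying block correlation structure so that every
    pipeline stage can be validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
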