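Package: fateinfo
Title: Forecasting Single-Cell Death Times from Initial Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how much information a cell's initial reporter
    expression carries about its fate under antibiotic exposure. Provides a
    stochastic simulator of single-cell time-kill experiments (heterogeneous
    initial fluorescence, expression-linked death times on a fixed imaging
    frame grid with right-censoring), equal-frequency (decile) binning,
    population killing curves and per-bin cumulative-death heatmaps, a binary
    mutual-information statistic over time with peak extraction, a permutation
    null for significance assessment, and killing-time spread summaries with
    Savitzky-Golay smoothing across expression deciles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
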