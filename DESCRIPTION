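Package: scedab
Title: Descriptive Analysis of Two-Phase Single-Case (AB) Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a single behavioural measure recorded over
    consecutive sessions in a baseline (A) phase followed by an intervention
    (B) phase. Implements the Non-overlap of All Pairs (NAP) effect size with
    its pairwise-count decomposition, the Slope and Level Change (SLC)
    detrending estimator, and the quantitative constructions behind structured
    visual analysis: range lines, central-tendency lines, two-standard-
    deviation bands, per-phase least-squares trend lines, and the split-middle
    trend with a projected stability envelope. A synthetic AB-series generator
    with linear trend, level and slope change and AR(1) serial dependence
    supports testing and null calibration, and an analysis report composes the
    visual, quantitative and substantive (clinical cut-off) assessments into a
    machine-readable summary with plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
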