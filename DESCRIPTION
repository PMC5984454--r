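Package: rankcbr
Title: Rank-Weighted Case-Based Reasoning for Plasma Thermogram Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies plasma proteomic thermograms (differential scanning
    calorimetry excess heat capacity profiles) by case-based reasoning with
    rank-order similarity. Per-feature local distances (squared Euclidean for
    scalar features, discrete Frechet for the full curve) are converted to
    dense ranks and combined into a weighted global similarity; feature
    weights are estimated from Wilcoxon rank-sum p-values, entropy, or
    logistic-regression Wald statistics. Includes a thermogram feature
    extractor based on Gaussian kernel regression, k-nearest-neighbour and
    composite-coefficient (SCUCC) baselines, a stratified cross-validation
    harness with precision/recall/F-1/G-measure reporting, and a seeded
    generator of synthetic two-class thermogram cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
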