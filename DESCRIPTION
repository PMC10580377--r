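Package: kataegisr
Title: Kataegis Detection by Changepoint Analysis of Intermutation Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects kataegis (clustered somatic hypermutation) in somatic
    variant calls. Per-chromosome intermutation distances are segmented by
    penalized changepoint detection under an exponential observation model
    (PELT, with BinSeg, SegNeigh and AMOC alternatives), segments are
    annotated with mutation rates, and loci are called under static or
    sample-adaptive intermutation-distance cutoffs. Ships a labelled
    synthetic-sample generator, per-variant classification metrics for
    benchmarking detectors, and rainfall plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
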