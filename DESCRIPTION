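Package: vgfc
Title: Visibility-Graph Analysis of Parcellated fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps parcellated resting-state fMRI time series to natural
    visibility graphs and analyses them with graph-theoretic tools. Builds
    binary and Euclidean-reciprocal weighted visibility graphs, extracts five
    global graph features per brain region (average weighted degree, average
    path length, global clustering coefficient, number of Walktrap
    communities, and modularity), fits power laws to degree distributions,
    estimates degree-synchrony functional connectivity between regions,
    quantifies the impact of head motion (framewise displacement) on the
    features, and assesses test-retest reliability with two-way
    absolute-agreement intraclass correlation. Includes a synthetic
    two-session fMRI cohort generator with known subject stability, community
    structure and motion contamination, so every stage of the pipeline can be
    run and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
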