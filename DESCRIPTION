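Package: tidyvss
Title: Two-Phase Tree-Based Prediction of Human Volume of Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase pipeline for predicting the human steady-state volume
    of distribution (Vss) of drug-like compounds from molecular descriptors.
    Phase one learns per-tissue log10 tissue:plasma partition coefficient
    (log Kt:p) regressors from descriptor tables with heavy per-tissue
    missingness; phase two feeds the predicted log Kt:p values back in as
    additional descriptors (optionally screened by correlation-based feature
    selection with genetic search) to learn log10 Vss regressors. Learners are
    M5-family model trees, regression trees, reduced-error-pruned trees,
    If-Then regression rules and bagging ensembles, all written here from
    scratch; models are evaluated by cross-validated mean absolute error and
    external-set geometric mean fold error, with applicability-domain and
    noise-sensitivity analyses. A seeded synthetic-data generator with a
    planted physiological signal stands in for proprietary descriptor software
    and curated partition-coefficient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
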