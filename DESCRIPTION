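Package: domfluor
Title: Predicting a Terrestrial Fluorescence Proxy from LC-FTMS Molecular
    Formula Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the terrestrial dissolved organic matter
    fluorescence proxy C475 (a PARAFAC component with emission maximum at
    475 nm) from liquid-chromatography Fourier-transform mass spectrometry
    (LC-FTMS) molecular formula intensity tables. Covers CHNOS formula
    parsing and double-bond-equivalent chemistry, conversion of long tables
    to time-aware and time-agnostic wide feature tables, feature elimination
    (ubiquitous, low-variance), compositional normalizations (DOC, sum,
    ubiquitous sum, additive log-ratio with zero replacement), benchmarking
    of elastic-net, random-forest and support-vector regressions over
    grid-searched repeated cross-validation, recursive feature elimination
    with out-of-bag permutation importance, tree-exact SHAP values, and
    SHAP-weighted elemental composition of terrestrial markers. Includes a
    seeded synthetic-data generator emulating a terrestrial/marine two
    end-member mixture so the full pipeline is testable without ship data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    kernlab,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
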