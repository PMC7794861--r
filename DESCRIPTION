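Package: grsmr
Title: Bidirectional Mendelian Randomization with Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional Mendelian randomization (MR) between a
    continuous exposure (body-mass index, kg/m^2) and a binary outcome
    (atopic dermatitis): harmonization of GWAS summary statistics, weighted
    genetic risk scores with instrument-strength and confounder diagnostics,
    one-sample (2SLS and logistic ratio) and two-sample (inverse-variance
    weighted, MR-Egger, weighted median) estimators with Cochran's Q and
    pleiotropy sensitivity statistics, doubling-of-odds scaling for
    binary-exposure effects, fixed-effect and DerSimonian-Laird meta-analytic
    pooling, and a synthetic-data generator that emulates the
    genotype-exposure-outcome structure (confounding, pleiotropy, reverse
    causation) so every stage is testable by simulation.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
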