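Package: tsplogit
Title: Top-Scoring Pair Logistic Regression for Binary Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based scoring of gene pairs (the top-scoring pair method) on
    expression matrices, logistic models that combine pair indicators with
    clinical covariates, repeated stratified k-fold cross-validation with
    in-fold feature selection and AUC-based model selection, a one-gene-at-a-time
    t-test baseline, and a synthetic-data generator that plants reversal gene
    pairs with marginally matched expression so every stage of the pipeline has
    a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
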