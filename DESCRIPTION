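Package: puriboost
Title: Tumor Purity Prediction from Gene Expression with Boosted Tree Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tumor sample purity (the fraction of cancer cells in a
    bulk tumor sample) from RNA-seq gene expression. Fits an ensemble of
    stochastic gradient-boosted regression trees on logit-transformed purity
    values over repeated k-fold cross-validation partitions, averages the
    resulting models into a bagged predictor, aggregates normalized split-gain
    importance scores across models to rank genes and extract small marker
    panels, and assesses significance with a label-permutation test. Includes
    a synthetic tumor/stroma admixture generator for benchmarking, and a
    pseudo-bulk bridge that aggregates single-cell counts into bulk-like
    profiles and harmonizes them with a reference training set so that models
    trained on bulk data can be validated against cell-type-derived purity
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
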