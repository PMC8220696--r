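Package: wgdipc
Title: Weighted Generalized Dipeptide Composition and Multi-Regression
    Ensemble Feature Selection for Protein Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences with dipeptide composition, gapped
    (generalized) dipeptide composition and their weighted fusion (W-GDipC),
    and selects discriminative sequence features with a two-stage
    multi-regression ensemble (LRMR-Ri) that combines Lasso, Ridge, maximal
    information coefficient and Relief filters. Includes a cross-validated
    classification harness (support vector machine, decision tree,
    stochastic gradient descent) with accuracy, recall, precision, F-measure
    and Matthews correlation coefficient reporting, and a synthetic sequence
    generator with planted class-discriminative dipeptides so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    rpart,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
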