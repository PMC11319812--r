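Package: smrnet
Title: Provincial Mortality Ratio Modelling with Random Forests, Boruta
    Selection and Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial analysis of cause-specific provincial mortality.
    Computes standardized mortality ratios (SMR) by indirect age
    standardization, predicts SMR from environmental and socio-economic
    indicator panels with linear and random-forest models under repeated
    k-fold cross-validation, selects all-relevant predictors with a
    shadow-feature (Boruta-style) wrapper built on per-tree permutation
    importance, checks robustness by appending centrality features from an
    entropy-thresholded province similarity network, and attributes
    predictions to features with exact and tree-ensemble Shapley values.
    Includes a synthetic-data module that generates indicator panels and
    age-stratified mortality with planted effects, so the whole pipeline is
    testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
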