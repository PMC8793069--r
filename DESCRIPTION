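Package: walkboost
Title: Network-Propagation Features and Gradient-Boosted Trees for Disease-Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes from a gene-interaction
    network. Genes are embedded by random-walk-with-restart diffusion over
    the network, and a gradient-boosted ensemble of CART regression trees
    (implemented from first principles, with logistic or squared loss)
    separates known disease genes from sampled negatives. Includes balanced
    negative sampling, stratified k-fold cross-validation with AUC/AUPR
    computed from the Mann-Whitney and average-precision definitions, a
    stochastic-block-model generator for planted disease modules, and a
    command-line pipeline (build, featurize, crossval, rank).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    methods,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse
Config/testthat/edition: 3
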