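Package: treeglasso
Title: Joint Estimation of Tree-Related Sparse Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Jointly estimates sparse Gaussian Markov networks for multiple
    cell states related by a phenotypic tree. Each gene's neighborhood is
    recovered by L1-penalized regression across all states simultaneously,
    with total-variation fusion penalties that encourage networks of
    phenotypically adjacent states to share structure while allowing sparse
    rewiring. Includes a tree-structured synthetic network simulator,
    precision-recall evaluation against static and independent baselines,
    microarray probe-level preprocessing (cyclic loess, median polish,
    fold-change filtering), differential-network and hub extraction, gene-set
    over-representation tests, ANOVA/t-test screens, and quartile-stratified
    Kaplan-Meier survival screening of hub genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
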