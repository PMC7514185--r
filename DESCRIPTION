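Package: mepnet
Title: Maximum-Entropy Effective Interactions of Pulse-Coupled Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate the anatomical coupling structure of
    pulse-coupled binary-state networks to the effective interactions of
    the maximum-entropy distribution of their network states. Provides an
    event-handling conductance-based integrate-and-fire network simulator,
    spike-train binarization and empirical state distributions, exact
    full-order effective-interaction solvers (Moebius inversion and the
    conditional log-odds recursion) plus an iterative-scaling fit for
    low-order models, a conditional-dependence statistic with
    shuffle-surrogate nulls, and graph-structural prediction of vanishing
    interactions via clique counting on the dependency graph, including
    the Erdos-Renyi ensemble experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
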