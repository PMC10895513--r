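Package: famnet
Title: Family Symptom Networks via Unregularised Gaussian Graphical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of partial-correlation symptom networks in
    mother-father-child trios. Provides a synthetic family symptom generator
    with a known sparse partial-correlation structure, Spearman correlation
    preprocessing with node-redundancy screening, unregularised Gaussian
    graphical model estimation with stepwise BIC model selection, strength and
    bridge-strength centrality with top-proportion bridge flagging,
    case-dropping bootstrap stability (CS coefficient), edge-weight bootstrap
    confidence intervals, and a permutation network comparison test for
    split-half replication. A three-step pipeline reproduces the full
    analysis: parent symptom network, cross-parent bridge symptoms, and
    re-estimation with a child emotional-difficulties factor score node.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
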