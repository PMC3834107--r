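Package: ordercause
Title: Causal Gene Network Inference from Observational and Knock-Out
    Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of direct and total causal effects among genes
    from an arbitrary mixture of observational (wild-type) and intervention
    (knock-out or knock-down) expression data, under causal Gaussian Bayesian
    networks. Causal node orderings are explored by a Metropolis-Hastings
    sampler with a Mallows proposal distribution sampled by repeated
    insertion; for each ordering the model parameters (residual means,
    residual standard deviations and edge weights) are maximized analytically
    by profile likelihood. Includes a structural-equation simulator for
    arbitrary intervention designs, the standard knock-out benchmark designs
    (observational, mixed, partial, multiple and hidden-gene), and evaluation
    of estimated effect matrices by AUROC, AUPRC, Spearman correlation and
    mean squared error.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
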