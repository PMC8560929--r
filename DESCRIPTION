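Package: vepmap
Title: Bayesian Identification of Seizure Propagation Patterns from
    Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates seizure propagation on connectome-coupled networks of
    Epileptor neural-mass oscillators, projects source activity to
    stereotactic-EEG (SEEG) sensors through an inverse-square gain matrix,
    extracts log-power data features, and inverts a hierarchical generative
    model (deterministic 2D Epileptor latent dynamics with a Gaussian
    observation likelihood) by maximum a posteriori (MAP) optimization with
    L-BFGS. Inferred source trajectories are converted to per-region seizure
    onset times and epileptogenic-zone / propagation-zone labels, with
    precision-recall and confusion-matrix evaluation against a clinical
    hypothesis and robustness experiments over observation noise and
    optimizer initialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    tools,
    signal,
    withr,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
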