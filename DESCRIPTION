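Package: tonicnet
Title: Tonic Monoamine Concentrations from Square-Wave Voltammetry by
    Semi-Supervised Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for resolving tonic concentrations
    of dopamine, norepinephrine, and serotonin from multiple cyclic square-wave
    voltammetry (M-CSWV) recordings. Provides a synthetic voltammogram generator
    with realistic electrode-to-electrode variability, dynamic background
    subtraction and heatmap preprocessing, six shallow calibration baselines
    (support vector regression, principal components regression, partial least
    squares, lasso, ridge, elastic net), and a convolutional autoencoder trained
    with a three-phase semi-supervised transfer-learning schedule that adapts to
    unlabeled in-vivo recordings. Includes within- and across-electrode
    evaluation protocols, interferent selectivity checks, and simulated
    pharmacology (cocaine, oxycodone) tracking scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
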