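Package: tnvae
Title: Predictive Variational Autoencoders for Robust Latent
    Representations of Time Series
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for learning low-dimensional latent representations of
    multivariate time series with variational autoencoders (VAEs), with an
    emphasis on robustness. Implements the Time-Neighbor VAE (TN-VAE), a
    VAE whose objective predicts the next time point rather than
    reconstructing the current one, and the Neighbor Loss model-selection
    metric, which scores the temporal smoothness of a latent trajectory.
    Includes simulators for sleep-like hidden-Markov-model data and noisy
    spiral manifolds with known ground truth, evaluation metrics
    (silhouette score, generalized Procrustes encoding distance,
    per-cluster moment diagnostics), an ensemble training engine over
    hyperparameter grids, and model-selection comparisons between
    validation-loss and Neighbor-Loss criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
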