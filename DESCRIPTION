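Package: embedal
Title: Active Learning with Variational Deep Embeddings
Version: 0.1.0
Authors@R:
    person("Embedal", "Developers", email = "embedal@example.org", role = c("aut", "cre"))
Description: Pool-based active learning in a learned latent space. Implements
    variational deep embedding (a variational autoencoder with a Gaussian
    mixture prior) for unsupervised representation learning and clustering,
    a latent-space multilayer-perceptron task classifier with Monte Carlo
    predictive uncertainty, and a three-score acquisition function combining
    predictive entropy, cluster representativeness and batch diversity with
    greedy budget-constrained query selection. Ships a synthetic
    Gaussian-mixture benchmark generator with known cluster ground truth, a
    full experiment harness (random and maximum-entropy baselines, per-round
    accuracy/micro-F1/AUC learning curves, multi-seed averaging) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
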