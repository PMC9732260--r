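# Shared test fixtures: small configurations and datasets built in code.

tiny_vade_config <- function(...) {
  defaults <- list(latent_dim = 2L, n_clusters = 3L,
                   encoder_layer_sizes = c(16L, 16L),
                   decoder_layer_sizes = c(16L, 16L),
                   pretrain_epochs = 5L, train_epochs = 5L,
                   learning_rate = 1e-3, batch_size = 64L, seed = 1L)
  do.call(vade_config, utils::modifyList(defaults, list(...)))
}

tiny_task_config <- function(...) {
  defaults <- list(hidden_layer_sizes = c(16L, 8L), learning_rate = 5e-3,
                   epochs = 40L, batch_size = 64L, mc_samples_L = 3L, seed = 1L)
  do.call(task_config, utils::modifyList(defaults, list(...)))
}

sep_dataset <- function(n = 300L, sep = 6, seed = 1L, obs_dim = 16L,
                        latent_dim = 2L, C = 3L, noise = 0.05, ...) {
  generate_dataset(synthetic_spec(
    n_samples = n, n_classes = C, latent_dim = latent_dim,
    observation_dim = obs_dim, cluster_separation = sep,
    observation_noise_sd = noise, seed = seed, ...))
}

# Wrap a bare probability matrix as a predictive distribution.
list_pred <- function(P) {
  structure(list(probabilities = P,
                 mc_draws = array(P, c(1L, nrow(P), ncol(P)))),
            class = "predictive_distribution")
}

# A small trained model reused across tests (computed once per test run).
cached_model <- local({
  env <- new.env()
  function() {
    if (is.null(env$model)) {
      env$ds <- sep_dataset(n = 400L, sep = 6, seed = 3L)
      env$model <- vade_train(env$ds, tiny_vade_config(train_epochs = 4L))
    }
    list(model = env$model, ds = env$ds)
  }
})
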