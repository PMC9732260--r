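#' Configuration for the variational deep embedding model
#'
#' A variational autoencoder whose latent prior is a Gaussian mixture:
#' generatively, a cluster `c ~ Cat(pi)` picks a diagonal Gaussian
#' `z ~ N(mu_c, sigma_c^2)` and a decoder network maps `z` to the
#' observation. An encoder network amortizes the variational posterior
#' `q(z|x) = N(mu(x), diag(exp(logvar(x))))`; training maximizes the
#' evidence lower bound by stochastic gradient ascent with the
#' reparameterization trick.
#'
#' @param latent_dim latent dimension
#' @param n_clusters number of mixture components (defaults to the number of
#'   classes of the dataset when used through the experiment harness)
#' @param encoder_layer_sizes hidden-layer widths of the encoder
#' @param decoder_layer_sizes hidden-layer widths of the decoder
#' @param pretrain_epochs autoencoder pretraining epochs
#' @param train_epochs joint ELBO-training epochs
#' @param learning_rate Adam learning rate for both phases
#' @param batch_size minibatch size (64 matches the reference protocol)
#' @param mc_samples_L Monte Carlo draws per ELBO evaluation during training
#' @param likelihood observation model: `"gaussian"` (unit variance) for
#'   real-valued features or `"bernoulli"` for features in `[0, 1]`
#' @param seed integer seed controlling all randomness
#' @return an object of class `vade_config`
#' @export
vade_config <- function(latent_dim = 10L,
                        n_clusters = NULL,
                        encoder_layer_sizes = c(256L, 256L),
                        decoder_layer_sizes = c(256L, 256L),
                        pretrain_epochs = 20L,
                        train_epochs = 30L,
                        learning_rate = 1e-3,
                        batch_size = 64L,
                        mc_samples_L = 1L,
                        likelihood = c("gaussian", "bernoulli"),
                        seed = 1L) {
  likelihood <- match.arg(likelihood)
  if (!is.null(n_clusters) && n_clusters < 1) abort_field("n_clusters", "must be >= 1")
  if (latent_dim < 1) abort_field("latent_dim", "must be >= 1")
  if (batch_size < 1) abort_field("batch_size", "must be >= 1")
  if (learning_rate <= 0) abort_field("learning_rate", "must be positive")
  if (mc_samples_L < 1) abort_field("mc_samples_L", "must be >= 1")
  structure(list(
    latent_dim = as.integer(latent_dim),
    n_clusters = if (!is.null(n_clusters)) as.integer(n_clusters),
    encoder_layer_sizes = as.integer(encoder_layer_sizes),
    decoder_layer_sizes = as.integer(decoder_layer_sizes),
    pretrain_epochs = as.integer(pretrain_epochs),
    train_epochs = as.integer(train_epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    mc_samples_L = as.integer(mc_samples_L), likelihood = likelihood,
    seed = as.integer(seed)
  ), class = "vade_config")
}

LOGVAR_CLAMP <- 8

# Build encoder (outputs [mu | logvar], 2 * latent_dim columns) and decoder.
# The logvar head is initialized near a small variance so early reparameterized
# draws stay close to the mean.
vade_init_nets <- function(input_dim, config) {
  enc <- mlp_new(c(input_dim, config$encoder_layer_sizes, 2L * config$latent_dim),
                 activation = "tanh", out = "identity")
  nl <- length(enc$layers)
  J <- config$latent_dim
  lv_cols <- J + seq_len(J)
  enc$layers[[nl]]$W[, lv_cols] <- enc$layers[[nl]]$W[, lv_cols] * 0.01
  enc$layers[[nl]]$b[lv_cols] <- -3
  dec <- mlp_new(c(J, config$decoder_layer_sizes, input_dim),
                 activation = "tanh", out = "identity")
  list(encoder = enc, decoder = dec)
}

encoder_heads <- function(enc_out, J) {
  mu <- enc_out[, seq_len(J), drop = FALSE]
  lv <- enc_out[, J + seq_len(J), drop = FALSE]
  list(mu = mu,
       lv = pmin(pmax(lv, -LOGVAR_CLAMP), LOGVAR_CLAMP),
       lv_mask = (lv > -LOGVAR_CLAMP & lv < LOGVAR_CLAMP) + 0)
}

# log p(x|z) per sample and its gradient wrt the decoder pre-activation.
recon_loglik <- function(X, dec_out, likelihood) {
  if (likelihood == "gaussian") {
    D <- X - dec_out
    list(ll = -0.5 * (rowSums(D * D) + ncol(X) * log(2 * pi)), dpre = D)
  } else {
    P <- 1 / (1 + exp(-dec_out))
    Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    list(ll = rowSums(X * log(Pc) + (1 - X) * log(1 - Pc)), dpre = X - P)
  }
}

# Evidence lower bound of a Gaussian-mixture-prior VAE, estimated with L
# reparameterized draws for the reconstruction term; the prior/entropy terms
# are closed-form in (mu, logvar) with q(c|x) set to the mixture
# responsibility of the variational mean (which makes the KL between q(z|x)
# and p(c|z) vanish by construction). Optionally returns ascent gradients
# for all parameters, derived analytically (finite-difference checked in the
# test suite).
vade_elbo_impl <- function(X, encoder, decoder, prior, L, likelihood,
                           epsilon = NULL, want_grads = FALSE) {
  X <- as_matrix_features(X)
  n <- nrow(X)
  J <- ncol(prior$means)
  K <- nrow(prior$means)
  encf <- mlp_forward(encoder, X)
  heads <- encoder_heads(encf$out, J)
  mu <- heads$mu; lv <- heads$lv
  sig2 <- exp(lv)
  sig <- exp(lv / 2)

  M <- prior$means
  Tm <- log(pmax(prior$variances, GMM_VAR_FLOOR))  # K x J log-variances
  eT <- exp(-Tm)                                   # K x J precisions
  logpi <- log(pmax(prior$weights, 1e-300))

  # l_{nk} = log pi_k + log N(mu_n; m_k, s_k^2); gamma = row-softmax(l)
  lmat <- matrix(0, n, K)
  for (k in seq_len(K)) {
    D <- mu - matrix(M[k, ], n, J, byrow = TRUE)
    lmat[, k] <- logpi[k] - 0.5 * (J * log(2 * pi) + sum(Tm[k, ]) + (D * D) %*% eT[k, ])
  }
  gamma <- softmax_rows(lmat)
  # a_{nk} = l_{nk} - 0.5 * sum_j sigma^2_{nj} / s^2_{kj}
  U <- 0.5 * (sig2 %*% t(eT))
  amat <- lmat - U
  loggamma <- log(pmax(gamma, 1e-300))
  kl_part <- rowSums(gamma * (amat - loggamma)) + 0.5 * rowSums(lv + 1 + log(2 * pi))

  if (is.null(epsilon)) {
    eps_draw <- function(l) matrix(stats::rnorm(n * J), n, J)
  } else {
    stopifnot(length(dim(epsilon)) == 3L, dim(epsilon)[1L] >= L)
    eps_draw <- function(l) matrix(epsilon[l, , ], n, J)
  }

  rec <- numeric(n)
  dec_grads <- NULL
  dmu_rec <- matrix(0, n, J)
  dlv_rec <- matrix(0, n, J)
  rec_draws <- matrix(0, n, L)
  for (l in seq_len(L)) {
    eps <- eps_draw(l)
    Zl <- mu + sig * eps
    decf <- mlp_forward(decoder, Zl)
    rl <- recon_loglik(X, decf$out, likelihood)
    rec_draws[, l] <- rl$ll
    rec <- rec + rl$ll / L
    if (want_grads) {
      bk <- mlp_backward(decoder, decf, rl$dpre / (L * n), dout_is_dz = TRUE)
      dec_grads <- if (is.null(dec_grads)) bk$grads else
        tree_map2(`+`, dec_grads, bk$grads)
      dmu_rec <- dmu_rec + bk$dX
      dlv_rec <- dlv_rec + bk$dX * (0.5 * sig * eps)
    }
  }

  elbo_n <- rec + kl_part
  elbo <- mean(elbo_n)
  if (!is.finite(elbo)) {
    bad <- if (!all(is.finite(rec))) "reconstruction term" else "KL/prior term"
    stop(sprintf("non-finite ELBO (%s)", bad), call. = FALSE)
  }
  out <- list(elbo = elbo, per_sample = elbo_n,
              reconstruction = mean(rec), kl_part = mean(kl_part),
              rec_draws = rec_draws, mu = mu, lv = lv, gamma = gamma)
  if (!want_grads) return(out)

  # ---- ascent gradients of mean ELBO ---------------------------------------
  # phi = dS/dl through the softmax; Psi = gamma + phi collects the direct
  # (through a) and indirect (through gamma) channels that share dl = da.
  s_n <- rowSums(gamma * (amat - loggamma))
  phi <- gamma * ((amat - loggamma) - s_n)
  Psi <- gamma + phi

  dmu_kl <- matrix(0, n, J)
  dlv_kl <- 0.5  # from the entropy of q(z|x)
  dM <- matrix(0, K, J)
  dT <- matrix(0, K, J)
  for (k in seq_len(K)) {
    D <- mu - matrix(M[k, ], n, J, byrow = TRUE)
    DeT <- D * matrix(eT[k, ], n, J, byrow = TRUE)
    dmu_kl <- dmu_kl - Psi[, k] * DeT
    dM[k, ] <- colSums(Psi[, k] * DeT)
    s2eT <- sig2 * matrix(eT[k, ], n, J, byrow = TRUE)
    dT[k, ] <- colSums(-0.5 * Psi[, k] * (1 - D * DeT) + 0.5 * gamma[, k] * s2eT)
  }
  dlv_kl <- 0.5 - 0.5 * sig2 * (gamma %*% eT)
  dw <- colSums(Psi) - n * prior$weights  # sum_n (Psi_nk - pi_k)

  dmu <- dmu_rec + dmu_kl / n
  dlv <- dlv_rec + dlv_kl / n
  dM <- dM / n; dT <- dT / n; dw <- dw / n

  denc_out <- cbind(dmu, dlv * heads$lv_mask)
  bk_enc <- mlp_backward(encoder, encf, denc_out, dout_is_dz = FALSE)

  out$grads <- list(encoder = bk_enc$grads, decoder = dec_grads,
                    prior = list(w = dw, M = dM, T = dT))
  out
}

#' Evidence lower bound of the mixture-prior VAE
#'
#' Returns the per-batch mean ELBO: a Monte Carlo estimate (L
#' reparameterized draws) of the reconstruction term `E_q[log p(x|z)]` plus
#' closed-form prior, assignment-entropy and posterior-entropy terms, with
#' `q(c|x)` taken as the mixture responsibility of the variational mean.
#' With a single mixture component this reduces exactly to the familiar VAE
#' bound, reconstruction minus `KL(q(z|x) || N(mu_1, sigma_1^2))`.
#'
#' @param batch feature matrix (rows = samples)
#' @param encoder,decoder network states (from [vade_train()] / [vade_pretrain()])
#' @param prior list with `weights`, `means` (K x J), `variances` (K x J)
#' @param L number of Monte Carlo draws (>= 1)
#' @param likelihood `"gaussian"` or `"bernoulli"`
#' @param epsilon optional fixed noise array `L x n x latent_dim` for
#'   deterministic evaluation
#' @return scalar mean ELBO, with per-sample values in attribute `"per_sample"`
#' @export
vade_elbo <- function(batch, encoder, decoder, prior, L = 1L,
                      likelihood = "gaussian", epsilon = NULL) {
  stopifnot(L >= 1L)
  validate_prior(prior)
  res <- vade_elbo_impl(batch, encoder, decoder, prior, L, likelihood, epsilon)
  structure(res$elbo, per_sample = res$per_sample,
            reconstruction = res$reconstruction, kl_part = res$kl_part)
}

validate_prior <- function(prior) {
  if (abs(sum(prior$weights) - 1) > 1e-6)
    abort_field("mixture_weights", "must sum to 1 within 1e-6")
  if (any(prior$variances <= 0))
    abort_field("variances", "must be strictly positive")
  invisible(prior)
}

#' Pretrain the autoencoder and initialize the mixture prior
#'
#' Trains a deterministic autoencoder (the variational mean head only, no
#' sampling) under reconstruction loss for `pretrain_epochs`, then fits a
#' classical diagonal-covariance Gaussian mixture to the resulting
#' embeddings to initialize the prior. All randomness derives from
#' `config$seed`.
#'
#' @param dataset an `al_dataset` or a feature matrix
#' @param config a [vade_config()]
#' @return list with `encoder`, `decoder`, `prior` and the per-epoch
#'   reconstruction-loss trace `recon_trace`
#' @export
vade_pretrain <- function(dataset, config) {
  X <- as_matrix_features(dataset)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(config$n_clusters))
    stop("n_clusters is not set; it defaults to the number of classes only inside the experiment harness", call. = FALSE)
  if (config$n_clusters > nrow(X))
    stop("n_clusters exceeds the number of samples", call. = FALSE)
  with_seed(config$seed, vade_pretrain_impl(X, config))
}

vade_pretrain_impl <- function(X, config) {
  nets <- vade_init_nets(ncol(X), config)
  enc <- nets$encoder
  dec <- nets$decoder
  J <- config$latent_dim
  n <- nrow(X)
  params <- list(enc = enc$layers, dec = dec$layers)
  opt <- adam_new(params, lr = config$learning_rate)
  trace <- numeric(config$pretrain_epochs)
  for (epoch in seq_len(config$pretrain_epochs)) {
    losses <- c()
    for (idx in minibatch_indices(n, config$batch_size)) {
      Xb <- X[idx, , drop = FALSE]
      encf <- mlp_forward(enc, Xb)
      Z <- encf$out[, seq_len(J), drop = FALSE]
      decf <- mlp_forward(dec, Z)
      D <- decf$out - Xb
      loss <- 0.5 * sum(D * D) / nrow(Xb)
      bk_dec <- mlp_backward(dec, decf, D / nrow(Xb), dout_is_dz = TRUE)
      dZ <- cbind(bk_dec$dX, matrix(0, nrow(Xb), J))
      bk_enc <- mlp_backward(enc, encf, dZ, dout_is_dz = FALSE)
      params <- adam_step(opt, list(enc = enc$layers, dec = dec$layers),
                          list(enc = bk_enc$grads, dec = bk_dec$grads))
      enc$layers <- params$enc
      dec$layers <- params$dec
      losses <- c(losses, loss)
    }
    trace[epoch] <- mean(losses)
  }
  emb <- mlp_forward(enc, X)$out[, seq_len(J), drop = FALSE]
  fit <- gmm_fit(emb, config$n_clusters)
  prior <- list(weights = fit$weights, means = fit$means,
                variances = pmax(fit$variances, GMM_VAR_FLOOR))
  list(encoder = enc, decoder = dec, prior = prior, recon_trace = trace)
}

#' Train the variational deep embedding model
#'
#' Runs [vade_pretrain()] and then jointly optimizes the encoder, decoder
#' and mixture-prior parameters by stochastic gradient ascent (Adam) on the
#' ELBO over minibatches for `train_epochs`. The prior is parameterized
#' unconstrained (softmax weights, log variances with a 1e-6 floor). Fully
#' seeded; `train_epochs = 0` returns the pretrained initialization
#' unchanged.
#'
#' @param dataset an `al_dataset` or feature matrix
#' @param config a [vade_config()]
#' @return an object of class `vade_model` with elements `encoder`,
#'   `decoder`, `prior`, `config`, `elbo_trace`, `recon_trace`
#' @export
vade_train <- function(dataset, config) {
  X <- as_matrix_features(dataset)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(config$n_clusters))
    stop("n_clusters is not set; it defaults to the number of classes only inside the experiment harness", call. = FALSE)
  if (config$n_clusters > nrow(X))
    stop("n_clusters exceeds the number of samples", call. = FALSE)
  with_seed(config$seed, {
    pre <- vade_pretrain_impl(X, config)
    enc <- pre$encoder; dec <- pre$decoder
    w_logit <- log(pmax(pre$prior$weights, 1e-10))
    M <- pre$prior$means
    Tm <- log(pmax(pre$prior$variances, GMM_VAR_FLOOR))
    trace <- numeric(config$train_epochs)
    if (config$train_epochs > 0L) {
      params <- list(enc = enc$layers, dec = dec$layers,
                     prior = list(w = w_logit, M = M, T = Tm))
      opt <- adam_new(params, lr = config$learning_rate)
      n <- nrow(X)
      for (epoch in seq_len(config$train_epochs)) {
        batch_elbos <- c()
        for (idx in minibatch_indices(n, config$batch_size)) {
          prior <- list(weights = softmax_rows(matrix(w_logit, 1L))[1L, ],
                        means = M, variances = pmax(exp(Tm), GMM_VAR_FLOOR))
          res <- tryCatch(
            vade_elbo_impl(X[idx, , drop = FALSE], enc, dec, prior,
                           config$mc_samples_L, config$likelihood,
                           want_grads = TRUE),
            error = function(e) stop(sprintf("ELBO diverged at epoch %d: %s",
                                             epoch, conditionMessage(e)), call. = FALSE)
          )
          batch_elbos <- c(batch_elbos, res$elbo)
          # Adam minimizes: negate the ascent gradients
          g <- tree_map2(function(a, b) -a,
                         list(enc = res$grads$encoder, dec = res$grads$decoder,
                              prior = res$grads$prior),
                         list(enc = res$grads$encoder, dec = res$grads$decoder,
                              prior = res$grads$prior))
          params <- adam_step(opt, list(enc = enc$layers, dec = dec$layers,
                                        prior = list(w = w_logit, M = M, T = Tm)), g)
          enc$layers <- params$enc
          dec$layers <- params$dec
          w_logit <- params$prior$w
          M <- params$prior$M
          Tm <- pmax(params$prior$T, log(GMM_VAR_FLOOR))
        }
        trace[epoch] <- mean(batch_elbos)
      }
    }
    prior <- list(weights = softmax_rows(matrix(w_logit, 1L))[1L, ],
                  means = M, variances = pmax(exp(Tm), GMM_VAR_FLOOR))
    structure(list(encoder = enc, decoder = dec, prior = prior,
                   config = config, elbo_trace = trace,
                   recon_trace = pre$recon_trace,
                   input_dim = ncol(X)),
              class = "vade_model")
  })
}

#' @export
print.vade_model <- function(x, ...) {
  cat(sprintf("<vade_model> input %d -> latent %d, %d mixture components\n",
              x$input_dim, x$config$latent_dim, nrow(x$prior$means)))
  invisible(x)
}

#' Encode features into the latent space
#'
#' Returns the variational mean and log-variance of `q(z|x)` and `L`
#' reparameterized draws `z = mu + exp(logvar/2) * eps`. The deterministic
#' embedding used by downstream scoring is the variational mean.
#'
#' @param model a `vade_model` (or pretrain result with an `encoder`)
#' @param features feature matrix; width must match the model input width
#' @param L number of Monte Carlo draws
#' @param epsilon optional fixed noise array `L x n x latent_dim`
#' @return list of class `latent_encoding`: `mean`, `log_variance` (n x J)
#'   and `samples` (`L x n x J` array)
#' @export
vade_encode <- function(model, features, L = 1L, epsilon = NULL) {
  X <- as_matrix_features(features)
  J <- model$config$latent_dim %||% (ncol(model$prior$means))
  expected <- model$input_dim %||% model$encoder$sizes[1L]
  if (ncol(X) != expected)
    stop(sprintf("shape error: features have %d columns, model expects %d",
                 ncol(X), expected), call. = FALSE)
  encf <- mlp_forward(model$encoder, X)
  heads <- encoder_heads(encf$out, J)
  n <- nrow(X)
  samples <- array(0, c(L, n, J))
  sig <- exp(heads$lv / 2)
  for (l in seq_len(L)) {
    eps <- if (is.null(epsilon)) matrix(stats::rnorm(n * J), n, J) else matrix(epsilon[l, , ], n, J)
    samples[l, , ] <- heads$mu + sig * eps
  }
  structure(list(mean = heads$mu, log_variance = heads$lv, samples = samples),
            class = "latent_encoding")
}

#' Posterior cluster responsibilities and hard assignments
#'
#' Computes `q(c|x)` by Bayes' rule over the mixture components evaluated at
#' the variational mean: `q(c|x) proportional to pi_c N(mu(x); m_c, s_c^2)`,
#' normalized in log space so rows sum to one even under extreme underflow.
#' Hard assignments are the row argmax (ties broken toward the lowest
#' cluster index); cluster ids are 0-based.
#'
#' @param model a `vade_model`
#' @param features feature matrix
#' @return list of class `cluster_posterior`: `responsibilities` (n x K) and
#'   `hard_assignment` (integer, 0-based)
#' @export
cluster_posterior <- function(model, features) {
  enc <- vade_encode(model, features, L = 1L,
                     epsilon = array(0, c(1L, nrow(as_matrix_features(features)),
                                          ncol(model$prior$means))))
  resp <- gmm_responsibilities(enc$mean, model$prior$weights,
                               model$prior$means, model$prior$variances)
  structure(list(responsibilities = resp,
                 hard_assignment = max.col(resp, ties.method = "first") - 1L),
            class = "cluster_posterior")
}

#' Save / load a trained model
#'
#' The checkpoint is a single serialized file holding encoder and decoder
#' weights, the mixture prior and the configuration; a reloaded model
#' produces bit-identical encodings.
#'
#' @param model a `vade_model`
#' @param path file path
#' @return `path` invisibly (`save_vade`); the model (`load_vade`)
#' @export
save_vade <- function(model, path) {
  stopifnot(inherits(model, "vade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_vade
#' @export
load_vade <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vade_model"))
  model
}
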