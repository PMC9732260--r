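# The embedding model: ELBO correctness, gradients, pretraining, training,
# encoding and cluster posteriors.

make_toy_parts <- function(input_dim = 5L, latent_dim = 2L, K = 3L,
                           enc_sizes = 4L, dec_sizes = 4L, seed = 42L) {
  cfg <- vade_config(latent_dim = latent_dim, n_clusters = K,
                     encoder_layer_sizes = enc_sizes,
                     decoder_layer_sizes = dec_sizes, seed = seed)
  withr::with_seed(seed, {
    nets <- embedal:::vade_init_nets(input_dim, cfg)
    prior <- list(weights = as.vector(embedal:::softmax_rows(matrix(rnorm(K), 1))),
                  means = matrix(rnorm(K * latent_dim), K, latent_dim),
                  variances = matrix(runif(K * latent_dim, 0.5, 2), K, latent_dim))
    list(enc = nets$encoder, dec = nets$decoder, prior = prior, cfg = cfg)
  })
}

test_that("analytic ELBO gradients match finite differences", {
  p <- make_toy_parts()
  X <- withr::with_seed(7, matrix(rnorm(4 * 5), 4, 5))
  eps <- withr::with_seed(8, array(rnorm(2 * 4 * 2), c(2, 4, 2)))
  f <- function(enc, dec, prior) {
    embedal:::vade_elbo_impl(X, enc, dec, prior, 2L, "gaussian", epsilon = eps)$elbo
  }
  res <- embedal:::vade_elbo_impl(X, p$enc, p$dec, p$prior, 2L, "gaussian",
                                  epsilon = eps, want_grads = TRUE)
  h <- 1e-6
  base <- f(p$enc, p$dec, p$prior)
  # encoder weight and bias, both layers
  for (li in 1:2) {
    e2 <- p$enc; e2$layers[[li]]$W[1, 2] <- e2$layers[[li]]$W[1, 2] + h
    expect_equal(res$grads$encoder[[li]]$W[1, 2], (f(e2, p$dec, p$prior) - base) / h,
                 tolerance = 1e-4)
    e2 <- p$enc; e2$layers[[li]]$b[1] <- e2$layers[[li]]$b[1] + h
    expect_equal(res$grads$encoder[[li]]$b[1], (f(e2, p$dec, p$prior) - base) / h,
                 tolerance = 1e-4)
  }
  d2 <- p$dec; d2$layers[[2]]$W[2, 3] <- d2$layers[[2]]$W[2, 3] + h
  expect_equal(res$grads$decoder[[2]]$W[2, 3], (f(p$enc, d2, p$prior) - base) / h,
               tolerance = 1e-4)
  # prior mean, log-variance and weight-logit channels
  q2 <- p$prior; q2$means[2, 1] <- q2$means[2, 1] + h
  expect_equal(res$grads$prior$M[2, 1], (f(p$enc, p$dec, q2) - base) / h,
               tolerance = 1e-4)
  q2 <- p$prior; q2$variances[1, 2] <- exp(log(q2$variances[1, 2]) + h)
  expect_equal(res$grads$prior$T[1, 2], (f(p$enc, p$dec, q2) - base) / h,
               tolerance = 1e-4)
  q2 <- p$prior
  wl <- log(q2$weights); wl[2] <- wl[2] + h
  q2$weights <- exp(wl) / sum(exp(wl))
  expect_equal(res$grads$prior$w[2], (f(p$enc, p$dec, q2) - base) / h,
               tolerance = 1e-4)
})

test_that("with one mixture component the ELBO equals the plain VAE bound", {
  p <- make_toy_parts(K = 1L)
  n <- 6L
  X <- withr::with_seed(9, matrix(rnorm(n * 5), n, 5))
  L <- 3L
  eps <- withr::with_seed(10, array(rnorm(L * n * 2), c(L, n, 2)))
  got <- vade_elbo(X, p$enc, p$dec, p$prior, L = L, likelihood = "gaussian",
                   epsilon = eps)
  # independent plain-VAE bound with the same fixed draws: reconstruction
  # (recomputed with explicit matrix algebra) minus KL(q || N(m1, s1^2))
  tanh_fwd <- function(net, Z) {
    H <- Z
    for (i in seq_along(net$layers)) {
      H <- H %*% net$layers[[i]]$W +
        matrix(net$layers[[i]]$b, nrow(H), length(net$layers[[i]]$b), byrow = TRUE)
      if (i < length(net$layers)) H <- tanh(H)
    }
    H
  }
  eo <- tanh_fwd(p$enc, X)
  mu <- eo[, 1:2]; lv <- pmin(pmax(eo[, 3:4], -8), 8)
  rec <- 0
  for (l in seq_len(L)) {
    Z <- mu + exp(lv / 2) * matrix(eps[l, , ], n, 2)
    XH <- tanh_fwd(p$dec, Z)
    rec <- rec + sum(-0.5 * ((X - XH)^2 + log(2 * pi))) / (L * n)
  }
  m1 <- p$prior$means[1, ]; v1 <- p$prior$variances[1, ]
  kl <- 0
  for (i in seq_len(n)) {
    kl <- kl + 0.5 * sum(log(v1) - lv[i, ] +
                           (exp(lv[i, ]) + (mu[i, ] - m1)^2) / v1 - 1) / n
  }
  expect_equal(as.numeric(got), rec - kl, tolerance = 1e-6)
})

test_that("ELBO KL part vanishes when q(z|x) sits exactly on a prior component", {
  # single component, encoder forced to output exactly (m1, log v1):
  # with a perfectly reconstructing decoder the bound reduces to the
  # reconstruction term; here we check the KL part alone is ~0.
  J <- 2L
  prior <- list(weights = 1, means = matrix(c(0.3, -0.7), 1L, J),
                variances = matrix(c(0.9, 1.4), 1L, J))
  enc <- embedal:::mlp_new(c(3L, 2L * J))
  enc$layers[[1]]$W[] <- 0
  enc$layers[[1]]$b <- c(prior$means[1, ], log(prior$variances[1, ]))
  dec <- embedal:::mlp_new(c(J, 3L))
  X <- matrix(rnorm(12), 4L, 3L)
  res <- embedal:::vade_elbo_impl(X, enc, dec, prior, 1L, "gaussian",
                                  epsilon = array(0, c(1L, 4L, J)))
  expect_equal(res$kl_part, 0, tolerance = 1e-6)
})

test_that("MC ELBO matches a closed-form bound on a linear-decoder toy within 3 SE", {
  # decoder with no hidden layer: E_q[log p(x|z)] has a closed form, so the
  # whole bound does; the MC estimate at large L must agree within MC error.
  p <- make_toy_parts(input_dim = 4L, dec_sizes = integer(0), seed = 5L)
  n <- 5L
  X <- withr::with_seed(11, matrix(rnorm(n * 4), n, 4))
  L <- 10000L
  res <- withr::with_seed(12,
    embedal:::vade_elbo_impl(X, p$enc, p$dec, p$prior, L, "gaussian"))
  # closed form, computed independently
  eo <- embedal:::mlp_forward(p$enc, X)$out
  mu <- eo[, 1:2]; lv <- pmin(pmax(eo[, 3:4], -8), 8)
  W <- p$dec$layers[[1]]$W; b0 <- p$dec$layers[[1]]$b
  rec_cf <- 0
  for (i in seq_len(n)) {
    m <- as.vector(mu[i, ] %*% W) + b0
    varterm <- as.vector(exp(lv[i, ]) %*% (W * W))
    rec_cf <- rec_cf + sum(-0.5 * ((X[i, ] - m)^2 + varterm + log(2 * pi))) / n
  }
  exact <- rec_cf + res$kl_part
  batch_means <- colMeans(res$rec_draws)        # one MC replicate per draw
  se <- stats::sd(batch_means) / sqrt(L)
  expect_lt(abs(res$elbo - exact), 3 * se + 1e-10)
})

test_that("pretraining reduces reconstruction loss and is deterministic", {
  X <- matrix(1.5, 40, 6)  # zero-variance data
  cfg <- tiny_vade_config(n_clusters = 2L, pretrain_epochs = 10L)
  pre <- vade_pretrain(X, cfg)
  expect_lte(pre$recon_trace[length(pre$recon_trace)], pre$recon_trace[1])
  ds <- sep_dataset(n = 120L, seed = 13L)
  a <- vade_pretrain(ds, tiny_vade_config(pretrain_epochs = 3L))
  b <- vade_pretrain(ds, tiny_vade_config(pretrain_epochs = 3L))
  expect_identical(a$prior, b$prior)
  expect_error(vade_pretrain(ds$features[1:2, ], tiny_vade_config()),
               "n_clusters")
})

test_that("GMM initialization recovers well-separated clusters", {
  ds <- sep_dataset(n = 400L, sep = 6, seed = 17L)
  pre <- vade_pretrain(ds, tiny_vade_config(pretrain_epochs = 10L))
  enc <- embedal:::mlp_forward(pre$encoder, ds$features)$out[, 1:2]
  resp <- embedal:::gmm_responsibilities(enc, pre$prior$weights,
                                         pre$prior$means, pre$prior$variances)
  hard <- max.col(resp, ties.method = "first") - 1L
  expect_gte(cluster_accuracy(hard, ds$true_cluster_ids), 0.9)
})

test_that("training improves the epoch-mean ELBO and is seed-deterministic", {
  improves <- vapply(1:3, function(s) {
    ds <- sep_dataset(n = 250L, seed = 20L + s)
    m <- vade_train(ds, tiny_vade_config(seed = s, train_epochs = 6L))
    m$elbo_trace[length(m$elbo_trace)] >= m$elbo_trace[1]
  }, logical(1))
  expect_gte(sum(improves), 2)  # majority of 3 seeds
  ds <- sep_dataset(n = 150L, seed = 30L)
  m1 <- vade_train(ds, tiny_vade_config(train_epochs = 3L))
  m2 <- vade_train(ds, tiny_vade_config(train_epochs = 3L))
  expect_equal(m1$prior$means, m2$prior$means, tolerance = 1e-6)
})

test_that("train_epochs = 0 returns the pretrained initialization unchanged", {
  ds <- sep_dataset(n = 150L, seed = 33L)
  cfg <- tiny_vade_config(train_epochs = 0L)
  pre <- vade_pretrain(ds, cfg)
  m <- vade_train(ds, cfg)
  expect_equal(m$prior$means, pre$prior$means)
  expect_equal(m$prior$weights, pre$prior$weights)
  expect_identical(m$encoder$layers, pre$encoder$layers)
  expect_length(m$elbo_trace, 0L)
})

test_that("encoding obeys the reparameterization contract", {
  mm <- cached_model()
  X <- mm$ds$features[1:7, ]
  eps <- withr::with_seed(40, array(rnorm(3 * 7 * 2), c(3, 7, 2)))
  enc <- vade_encode(mm$model, X, L = 3L, epsilon = eps)
  expect_equal(dim(enc$samples), c(3L, 7L, 2L))
  for (l in 1:3) {
    expect_equal(matrix(enc$samples[l, , ], 7, 2),
                 enc$mean + exp(enc$log_variance / 2) * matrix(eps[l, , ], 7, 2))
  }
  # duplicated rows encode identically
  encd <- vade_encode(mm$model, X[c(1, 1, 2), ], L = 1L,
                      epsilon = array(0, c(1, 3, 2)))
  expect_identical(encd$mean[1, ], encd$mean[2, ])
  expect_error(vade_encode(mm$model, X[, 1:5]), "shape")
})

test_that("cluster responsibilities follow Bayes' rule on a hand-computed toy", {
  prior <- list(weights = c(0.2, 0.3, 0.5),
                means = matrix(c(0, 0, 2, 1, -1, 3), 3, 2, byrow = TRUE),
                variances = matrix(c(1, 0.5, 2, 1, 0.25, 0.8), 3, 2, byrow = TRUE))
  Z <- matrix(c(0.5, -0.2, 2.1, 0.9, -1.3, 2.7, 10, -10), 4, 2, byrow = TRUE)
  got <- embedal:::gmm_responsibilities(Z, prior$weights, prior$means, prior$variances)
  # direct hand computation of Bayes' rule with dnorm products
  expected <- matrix(0, 4, 3)
  for (i in 1:4) {
    num <- vapply(1:3, function(k) {
      prior$weights[k] *
        prod(dnorm(Z[i, ], prior$means[k, ], sqrt(prior$variances[k, ])))
    }, numeric(1))
    expected[i, ] <- num / sum(num)
  }
  # row 4 underflows in the direct computation; compare the first three rows
  expect_equal(got[1:3, ], expected[1:3, ], tolerance = 1e-9)
  expect_equal(rowSums(got), rep(1, 4), tolerance = 1e-6)
  expect_false(anyNA(got))
})

test_that("responsibility symmetry and dominance limit cases hold", {
  # equidistant point under equal weights/variances -> uniform responsibilities
  prior <- list(weights = rep(1 / 3, 3),
                means = embedal:::cluster_mean_layout(3L, 2L, 4, 1),
                variances = matrix(1, 3, 2))
  z0 <- matrix(colMeans(prior$means), 1, 2)  # centroid is equidistant
  r <- embedal:::gmm_responsibilities(z0, prior$weights, prior$means, prior$variances)
  expect_equal(as.vector(r), rep(1 / 3, 3), tolerance = 1e-9)
  # point at component 2's mean with tiny variance there -> responsibility ~1
  prior$variances[2, ] <- 1e-4
  r2 <- embedal:::gmm_responsibilities(matrix(prior$means[2, ], 1), prior$weights,
                                       prior$means, prior$variances)
  expect_gte(r2[1, 2], 0.99)
})

test_that("responsibility rows sum to one even at extreme inputs", {
  prior <- list(weights = c(0.5, 0.5),
                means = matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
                variances = matrix(0.01, 2, 2))
  Z <- matrix(c(1e4, 1e4, -1e4, 1e4, 500, -500), 3, 2, byrow = TRUE)
  r <- embedal:::gmm_responsibilities(Z, prior$weights, prior$means, prior$variances)
  expect_equal(rowSums(r), rep(1, 3))
  expect_false(any(!is.finite(r)))
})

test_that("MC ELBO variance shrinks roughly as 1/L", {
  p <- make_toy_parts(seed = 51L)
  X <- withr::with_seed(52, matrix(rnorm(6 * 5), 6, 5))
  est <- function(L, reps) {
    vapply(seq_len(reps), function(i)
      as.numeric(vade_elbo(X, p$enc, p$dec, p$prior, L = L)), numeric(1))
  }
  withr::with_seed(53, {
    v1 <- var(est(1L, 60))
    v16 <- var(est(16L, 60))
    v256 <- var(est(256L, 30))
  })
  expect_gt(v1 / v16, 4)    # ideal 16, generous statistical slack
  expect_gt(v16 / v256, 4)  # ideal 16
})

test_that("a saved model reloads to bit-identical encodings", {
  mm <- cached_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_vade(mm$model, path)
  back <- load_vade(path)
  X <- mm$ds$features[1:5, ]
  e1 <- vade_encode(mm$model, X, epsilon = array(0, c(1, 5, 2)))
  e2 <- vade_encode(back, X, epsilon = array(0, c(1, 5, 2)))
  expect_identical(e1$mean, e2$mean)
})
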