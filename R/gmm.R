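# Diagonal-covariance Gaussian mixture: log densities, responsibilities and
# an EM fitter used to initialize the latent prior from pretrained
# embeddings. Variances are floored at `var_floor` throughout to prevent
# component collapse.

GMM_VAR_FLOOR <- 1e-6

# n x K matrix of log N(x_i; mean_k, diag(var_k))
gmm_log_dens <- function(X, means, variances) {
  X <- as_matrix_features(X)
  K <- nrow(means)
  n <- nrow(X)
  J <- ncol(X)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    v <- pmax(variances[k, ], GMM_VAR_FLOOR)
    D <- X - matrix(means[k, ], n, J, byrow = TRUE)
    out[, k] <- -0.5 * (J * log(2 * pi) + sum(log(v)) +
                          (D * D) %*% (1 / v))
  }
  out
}

# Posterior responsibilities q(c|x) computed in log space; rows sum to 1
# exactly even when all component densities underflow.
gmm_responsibilities <- function(X, weights, means, variances) {
  lp <- gmm_log_dens(X, means, variances) +
    matrix(log(pmax(weights, 1e-300)), nrow(as_matrix_features(X)), length(weights), byrow = TRUE)
  softmax_rows(lp)
}

gmm_loglik <- function(X, weights, means, variances) {
  lp <- gmm_log_dens(X, means, variances) +
    matrix(log(pmax(weights, 1e-300)), nrow(as_matrix_features(X)), length(weights), byrow = TRUE)
  sum(log_sum_exp_rows(lp))
}

# EM fit with kmeans initialization. Uses the caller's RNG stream (seed it
# with with_seed). Handles fewer distinct points than K by jittered init.
gmm_fit <- function(X, K, n_iter = 200L, tol = 1e-8) {
  X <- as_matrix_features(X)
  n <- nrow(X)
  J <- ncol(X)
  if (K > n) stop("more mixture components than samples", call. = FALSE)
  distinct <- nrow(unique(round(X, 10)))
  if (K == 1L) {
    means <- matrix(colMeans(X), 1L, J)
    variances <- matrix(pmax(apply(X, 2L, stats::var) * (n - 1) / n, GMM_VAR_FLOOR), 1L, J)
    if (n == 1L) variances[] <- GMM_VAR_FLOOR
    return(list(weights = 1, means = means, variances = variances,
                loglik = gmm_loglik(X, 1, means, variances)))
  }
  if (distinct >= K) {
    km <- stats::kmeans(X, centers = K, nstart = 5L, iter.max = 50L)
    means <- matrix(km$centers, K, J)
  } else {
    means <- X[sample.int(n, K, replace = TRUE), , drop = FALSE] +
      matrix(stats::rnorm(K * J, sd = 1e-3), K, J)
  }
  gv <- pmax(apply(X, 2L, stats::var) * (n - 1) / n, GMM_VAR_FLOOR)
  variances <- matrix(gv, K, J, byrow = TRUE)
  weights <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(n_iter)) {
    lp <- gmm_log_dens(X, means, variances) +
      matrix(log(pmax(weights, 1e-300)), n, K, byrow = TRUE)
    lse <- log_sum_exp_rows(lp)
    ll <- sum(lse)
    R <- exp(lp - lse)
    nk <- colSums(R)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- crossprod(R, X) / nk
    for (k in seq_len(K)) {
      D <- X - matrix(means[k, ], n, J, byrow = TRUE)
      variances[k, ] <- pmax(colSums(R[, k] * (D * D)) / nk[k], GMM_VAR_FLOOR)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(weights = weights, means = means, variances = variances,
       loglik = gmm_loglik(X, weights, means, variances))
}
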