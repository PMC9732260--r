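# Minimal dense-network machinery: forward, backprop, optimizers.
# No deep-learning framework is available in the target environment, so the
# few layer types the models need (affine + tanh/relu, identity/sigmoid/
# softmax heads) are implemented directly on base matrices. Gradients are
# verified against finite differences in the test suite.

mlp_new <- function(sizes, activation = "tanh", out = "identity") {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    fan_out <- sizes[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[i]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = numeric(fan_out)
    )
  }
  structure(list(layers = layers, sizes = sizes, activation = activation, out = out),
            class = "embedal_mlp")
}

act_apply <- function(kind, Z) {
  switch(kind,
    tanh = tanh(Z),
    relu = pmax(Z, 0),
    stop("unknown activation: ", kind)
  )
}

act_deriv <- function(kind, A, Z) {
  switch(kind,
    tanh = 1 - A * A,
    relu = (Z > 0) + 0,
    stop("unknown activation: ", kind)
  )
}

out_apply <- function(kind, Z) {
  switch(kind,
    identity = Z,
    sigmoid = 1 / (1 + exp(-Z)),
    softmax = softmax_rows(Z),
    stop("unknown output activation: ", kind)
  )
}

add_bias <- function(Z, b) {
  Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
}

# Forward pass; keeps activations for backprop.
mlp_forward <- function(net, X) {
  nl <- length(net$layers)
  A <- vector("list", nl + 1L)
  Zs <- vector("list", nl)
  A[[1L]] <- X
  H <- X
  for (i in seq_len(nl)) {
    Z <- add_bias(H %*% net$layers[[i]]$W, net$layers[[i]]$b)
    Zs[[i]] <- Z
    H <- if (i < nl) act_apply(net$activation, Z) else out_apply(net$out, Z)
    A[[i + 1L]] <- H
  }
  list(out = H, A = A, Z = Zs)
}

# Backward pass. `dout` is dLoss/d(output) unless `dout_is_dz`, in which case
# it is dLoss/d(final pre-activation) — used with softmax + cross-entropy and
# sigmoid + Bernoulli likelihood where that combination is simplest.
mlp_backward <- function(net, cache, dout, dout_is_dz = FALSE) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  dH <- NULL
  for (i in nl:1) {
    if (i == nl) {
      if (dout_is_dz) {
        dZ <- dout
      } else {
        dZ <- switch(net$out,
          identity = dout,
          sigmoid = dout * cache$A[[nl + 1L]] * (1 - cache$A[[nl + 1L]]),
          stop("softmax output requires dout_is_dz = TRUE")
        )
      }
    } else {
      dZ <- dH * act_deriv(net$activation, cache$A[[i + 1L]], cache$Z[[i]])
    }
    grads[[i]] <- list(W = crossprod(cache$A[[i]], dZ), b = colSums(dZ))
    dH <- tcrossprod(dZ, net$layers[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

# ---- optimizers on nested parameter trees -----------------------------------
# Parameters and gradients are nested lists whose leaves are numeric arrays.

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map3 <- function(f, a, b, d) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], d[[i]])
    out
  } else {
    f(a, b, d)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- tree_zero(params)
  e$v <- tree_zero(params)
  e$t <- 0L
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

# One Adam minimization step: params <- params - update(grads)
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g * g, opt$v, grads)
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  tree_map3(function(p, m, v) p - opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps),
            params, opt$m, opt$v)
}

sgdm_new <- function(params, lr, momentum = 0, weight_decay = 0) {
  e <- new.env(parent = emptyenv())
  e$vel <- tree_zero(params)
  e$lr <- lr; e$momentum <- momentum; e$weight_decay <- weight_decay
  e
}

# SGD with momentum; weight decay applied to weight matrices only (leaves
# named "W" in layer lists), the usual convention.
sgdm_step_net <- function(opt, net, grads) {
  for (i in seq_along(net$layers)) {
    gW <- grads[[i]]$W + opt$weight_decay * net$layers[[i]]$W
    gb <- grads[[i]]$b
    opt$vel[[i]]$W <- opt$momentum * opt$vel[[i]]$W - opt$lr * gW
    opt$vel[[i]]$b <- opt$momentum * opt$vel[[i]]$b - opt$lr * gb
    net$layers[[i]]$W <- net$layers[[i]]$W + opt$vel[[i]]$W
    net$layers[[i]]$b <- net$layers[[i]]$b + opt$vel[[i]]$b
  }
  net
}

minibatch_indices <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}
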