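#' Configuration for the latent-space task classifier
#'
#' A multilayer perceptron trained on the variational-mean embeddings of the
#' labeled pool by SGD with momentum, minimizing mean cross-entropy. The
#' defaults reproduce the reference protocol: a 5-weight-layer perceptron,
#' learning rate 1e-4, momentum 0.9, weight decay 0.005, batch size 64.
#'
#' @param hidden_layer_sizes hidden widths; with the output layer the default
#'   gives five weight layers
#' @param learning_rate SGD learning rate
#' @param momentum SGD momentum
#' @param weight_decay L2 penalty on weight matrices
#' @param batch_size minibatch size
#' @param epochs training epochs
#' @param mc_samples_L default Monte Carlo draws for predictive uncertainty
#' @param seed integer seed
#' @return an object of class `task_config`
#' @export
task_config <- function(hidden_layer_sizes = c(128L, 64L, 32L, 16L),
                        learning_rate = 1e-4,
                        momentum = 0.9,
                        weight_decay = 0.005,
                        batch_size = 64L,
                        epochs = 100L,
                        mc_samples_L = 10L,
                        seed = 1L) {
  if (learning_rate <= 0) abort_field("learning_rate", "must be positive")
  if (batch_size < 1) abort_field("batch_size", "must be >= 1")
  if (mc_samples_L < 1) abort_field("mc_samples_L", "must be >= 1")
  structure(list(
    hidden_layer_sizes = as.integer(hidden_layer_sizes),
    learning_rate = learning_rate, momentum = momentum,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), mc_samples_L = as.integer(mc_samples_L),
    seed = as.integer(seed)
  ), class = "task_config")
}

#' Train the task classifier on labeled embeddings
#'
#' Embeds the labeled features through the model's variational mean (pass
#' `model = NULL` to treat `labeled_features` as embeddings directly) and
#' minimizes mean cross-entropy by SGD with momentum and weight decay.
#'
#' @param model a `vade_model`, or `NULL`
#' @param labeled_features feature matrix of the labeled pool
#' @param labels integer class labels in `0 .. C-1`
#' @param config a [task_config()]
#' @param n_classes number of classes C; defaults to `max(labels) + 1`
#' @return object of class `classifier_state` with the network, `loss_trace`
#'   and `n_classes`
#' @export
train_classifier <- function(model, labeled_features, labels, config,
                             n_classes = NULL) {
  X <- as_matrix_features(labeled_features)
  if (nrow(X) == 0L) stop("empty labeled pool", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels length must match feature rows", call. = FALSE)
  C <- as.integer(n_classes %||% (max(labels) + 1L))
  if (any(labels < 0L) || any(labels >= C))
    stop(sprintf("label outside the class range [0, %d)", C), call. = FALSE)
  emb <- if (is.null(model)) X else vade_encode(model, X, L = 1L,
                                                epsilon = array(0, c(1L, nrow(X), model$config$latent_dim)))$mean
  n <- nrow(emb)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  with_seed(config$seed, {
    net <- mlp_new(c(ncol(emb), config$hidden_layer_sizes, C),
                   activation = "tanh", out = "softmax")
    opt <- sgdm_new(net$layers, lr = config$learning_rate,
                    momentum = config$momentum,
                    weight_decay = config$weight_decay)
    trace <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      losses <- c()
      for (idx in minibatch_indices(n, config$batch_size)) {
        f <- mlp_forward(net, emb[idx, , drop = FALSE])
        P <- pmin(pmax(f$out, 1e-12), 1)
        loss <- -sum(Y[idx, , drop = FALSE] * log(P)) / length(idx)
        dZ <- (f$out - Y[idx, , drop = FALSE]) / length(idx)
        bk <- mlp_backward(net, f, dZ, dout_is_dz = TRUE)
        net <- sgdm_step_net(opt, net, bk$grads)
        losses <- c(losses, loss)
      }
      trace[epoch] <- mean(losses)
    }
    structure(list(net = net, n_classes = C, loss_trace = trace,
                   config = config, input_dim = ncol(emb)),
              class = "classifier_state")
  })
}

#' Monte Carlo predictive distribution
#'
#' Draws `L` reparameterized latent samples per input through the model's
#' encoder, runs the classifier on each draw and averages the per-draw class
#' probabilities. With `model = NULL` the features are used as embeddings
#' and all draws coincide.
#'
#' @param model a `vade_model`, or `NULL`
#' @param classifier a `classifier_state`
#' @param features feature matrix
#' @param L number of Monte Carlo draws
#' @param epsilon optional fixed noise array `L x n x latent_dim`
#' @return object of class `predictive_distribution`: `probabilities`
#'   (`n x C`, rows on the simplex) and `mc_draws` (`L x n x C`)
#' @export
predict_classifier <- function(model, classifier, features,
                               L = classifier$config$mc_samples_L,
                               epsilon = NULL) {
  stopifnot(L >= 1L)
  X <- as_matrix_features(features)
  n <- nrow(X)
  C <- classifier$n_classes
  draws <- array(0, c(L, n, C))
  if (is.null(model)) {
    if (ncol(X) != classifier$input_dim)
      stop(sprintf("shape error: features have %d columns, classifier expects %d",
                   ncol(X), classifier$input_dim), call. = FALSE)
    P1 <- mlp_forward(classifier$net, X)$out
    for (l in seq_len(L)) draws[l, , ] <- P1
  } else {
    enc <- vade_encode(model, X, L = L, epsilon = epsilon)
    for (l in seq_len(L)) {
      Zl <- matrix(enc$samples[l, , ], n, model$config$latent_dim)
      draws[l, , ] <- mlp_forward(classifier$net, Zl)$out
    }
  }
  probs <- matrix(0, n, C)
  for (l in seq_len(L)) probs <- probs + matrix(draws[l, , ], n, C)
  probs <- probs / L
  structure(list(probabilities = probs, mc_draws = draws),
            class = "predictive_distribution")
}

#' Predictive-entropy uncertainty score
#'
#' `H(x) = -sum_i p(y=i|x) log p(y=i|x)` on the Monte-Carlo-averaged class
#' probabilities (natural logarithm, `0 log 0 = 0`). Nonnegative, bounded by
#' `log C`, maximal at the uniform distribution: the higher the predictive
#' entropy, the more uncertain the sample.
#'
#' @param pred a `predictive_distribution` or a probability matrix
#' @return numeric vector of per-sample entropies
#' @export
uncertainty_score <- function(pred) {
  P <- if (inherits(pred, "predictive_distribution")) pred$probabilities else as.matrix(pred)
  row_entropy(P)
}
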