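#' Similarity configuration for the sampling calculator
#'
#' @param kernel `"rbf"` (Gaussian kernel on Euclidean distance, values in
#'   `(0, 1]`) or `"cosine"` (values in `[-1, 1]`)
#' @param bandwidth_rule `"median_heuristic"` (rbf bandwidth = median of all
#'   pairwise distances) or `"fixed"`
#' @param fixed_bandwidth bandwidth sigma when `bandwidth_rule = "fixed"`
#' @return an object of class `similarity_config`
#' @export
similarity_config <- function(kernel = c("rbf", "cosine"),
                              bandwidth_rule = c("median_heuristic", "fixed"),
                              fixed_bandwidth = NULL) {
  kernel <- match.arg(kernel)
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (bandwidth_rule == "fixed") {
    if (is.null(fixed_bandwidth) || fixed_bandwidth <= 0)
      abort_field("fixed_bandwidth", "must be a positive scalar when bandwidth_rule = 'fixed'")
  }
  structure(list(kernel = kernel, bandwidth_rule = bandwidth_rule,
                 fixed_bandwidth = fixed_bandwidth),
            class = "similarity_config")
}

#' Selection weights for the composite acquisition score
#'
#' Weights of the representativeness (`r`) and diversity (`b`) terms in the
#' composite score `I = H + r * G + b * R`. In grid-search mode both are
#' restricted to the grid `{0.1, 0.5, 1, 5}`.
#'
#' @param r nonnegative representativeness weight
#' @param b nonnegative diversity weight
#' @return an object of class `score_weights`
#' @export
score_weights <- function(r = 1, b = 1) {
  if (r < 0) abort_field("r", "must be nonnegative")
  if (b < 0) abort_field("b", "must be nonnegative")
  structure(list(r = r, b = b), class = "score_weights")
}

#' Pairwise similarity matrix
#'
#' rbf: `sim(u, v) = exp(-||u - v||^2 / (2 sigma^2))` with sigma from the
#' median heuristic or fixed; cosine: the standard cosine of the two
#' vectors. Symmetric; diagonal 1 for rbf (and for cosine on nonzero rows).
#'
#' @param embeddings numeric matrix, rows = samples
#' @param config a [similarity_config()]
#' @return symmetric `n x n` similarity matrix
#' @export
pairwise_similarity <- function(embeddings, config = similarity_config()) {
  E <- as_matrix_features(embeddings)
  n <- nrow(E)
  if (config$kernel == "cosine") {
    nrm <- sqrt(rowSums(E * E))
    zero <- which(nrm == 0)
    if (length(zero) > 0)
      stop(sprintf("cosine similarity undefined for zero vector at row %d", zero[1L]),
           call. = FALSE)
    En <- E / nrm
    S <- tcrossprod(En)
    S <- pmin(pmax(S, -1), 1)
    return(S)
  }
  D2 <- pairwise_sqdist(E)
  sigma <- if (config$bandwidth_rule == "fixed") {
    config$fixed_bandwidth
  } else {
    if (n < 2L) stop("median heuristic needs at least 2 rows", call. = FALSE)
    d <- sqrt(D2[upper.tri(D2)])
    max(stats::median(d), 1e-12)
  }
  exp(-D2 / (2 * sigma^2))
}

pairwise_sqdist <- function(E) {
  sq <- rowSums(E * E)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(E)
  pmax(D2, 0)
}

#' Representativeness score G
#'
#' Mean similarity of each sample to the other members of its cluster (self
#' excluded). Samples near their cluster center score highest. Singleton
#' clusters score 0 by convention.
#'
#' @param embeddings numeric matrix over the candidate pool
#' @param cluster_ids cluster id per row (any coding)
#' @param sim_config a [similarity_config()]
#' @param similarity optional precomputed similarity matrix
#' @return numeric vector G over the candidate rows
#' @export
representativeness <- function(embeddings, cluster_ids,
                               sim_config = similarity_config(),
                               similarity = NULL) {
  E <- as_matrix_features(embeddings)
  if (length(cluster_ids) != nrow(E))
    stop("length mismatch between embeddings and cluster_ids", call. = FALSE)
  S <- similarity %||% pairwise_similarity(E, sim_config)
  G <- numeric(nrow(E))
  for (cl in unique(cluster_ids)) {
    idx <- which(cluster_ids == cl)
    if (length(idx) == 1L) {
      G[idx] <- 0
    } else {
      Ssub <- S[idx, idx, drop = FALSE]
      G[idx] <- (colSums(Ssub) - diag(Ssub)) / (length(idx) - 1L)
    }
  }
  G
}

#' Diversity score R of one candidate against the selected set
#'
#' `R(x) = -mean(sim(x, s) for s in S)`; 0 when S is empty. Penalizes
#' candidates similar to what has already been selected.
#'
#' @param candidate_index row index of the candidate
#' @param selected integer vector of already-selected row indices
#' @param similarity precomputed similarity matrix over the pool
#' @return scalar R
#' @export
diversity <- function(candidate_index, selected, similarity) {
  if (candidate_index %in% selected)
    stop("candidate is already in the selected set", call. = FALSE)
  if (length(selected) == 0L) return(0)
  -mean(similarity[candidate_index, selected])
}

# vectorized diversity for all candidates at once
diversity_all <- function(candidates, selected, similarity) {
  if (length(selected) == 0L) return(numeric(length(candidates)))
  -colMeans(matrix(similarity[selected, candidates, drop = FALSE],
                   length(selected), length(candidates)))
}

#' Composite acquisition score
#'
#' `I = H + r * G + b * R`, elementwise and exact. With `normalize = TRUE`
#' the entropy term is first divided by `log(n_classes)` so all three terms
#' are O(1).
#'
#' @param H uncertainty vector
#' @param G representativeness vector
#' @param R diversity vector
#' @param w a [score_weights()]
#' @param normalize divide H by `log(n_classes)` first
#' @param n_classes required when `normalize = TRUE`
#' @return numeric vector I
#' @export
composite_score <- function(H, G, R, w = score_weights(), normalize = FALSE,
                            n_classes = NULL) {
  if (length(G) != length(H) || length(R) != length(H))
    stop("H, G and R must have equal lengths", call. = FALSE)
  if (normalize) {
    if (is.null(n_classes)) stop("n_classes is required when normalize = TRUE", call. = FALSE)
    H <- H / log(n_classes)
  }
  H + w$r * G + w$b * R
}

#' Greedy budget-constrained selection
#'
#' Iterative greedy maximization of the composite score: uncertainty H and
#' representativeness G are computed once (they do not depend on the
#' selection), the diversity R of every remaining candidate is recomputed
#' against the growing selection S at every step, and the argmax of
#' `I = H + r G + b R` is appended (ties toward the lowest candidate index)
#' until `|S| = B` or the pool is exhausted.
#'
#' @param H uncertainty vector over the candidate pool
#' @param embeddings embedding matrix over the candidate pool (same order)
#' @param cluster_ids cluster id per candidate
#' @param B selection budget (>= 1)
#' @param w a [score_weights()]
#' @param sim_config a [similarity_config()]
#' @param normalize,n_classes passed to [composite_score()]
#' @return object of class `selection_result`: `selected` (indices into the
#'   candidate pool, in pick order) and `score_trace`, a data.frame with one
#'   row per (pick, candidate) giving H, G, R and I at that step
#' @export
greedy_select <- function(H, embeddings, cluster_ids, B,
                          w = score_weights(),
                          sim_config = similarity_config(),
                          normalize = FALSE, n_classes = NULL) {
  if (B < 1) stop("budget B must be >= 1", call. = FALSE)
  E <- as_matrix_features(embeddings)
  n <- nrow(E)
  if (n == 0L) stop("candidate pool is empty", call. = FALSE)
  if (length(H) != n) stop("H length must match the candidate pool", call. = FALSE)
  S <- if (n >= 2L || sim_config$bandwidth_rule == "fixed") {
    pairwise_similarity(E, sim_config)
  } else {
    matrix(1, 1L, 1L)
  }
  G <- representativeness(E, cluster_ids, sim_config, similarity = S)
  selected <- integer(0)
  remaining <- seq_len(n)
  trace <- vector("list", min(B, n))
  for (step in seq_len(min(B, n))) {
    R <- diversity_all(remaining, selected, S)
    I <- composite_score(H[remaining], G[remaining], R, w,
                         normalize = normalize, n_classes = n_classes)
    pick_pos <- which.max(I)  # first maximum = lowest candidate index
    pick <- remaining[pick_pos]
    trace[[step]] <- data.frame(pick = step, candidate = remaining,
                                H = H[remaining], G = G[remaining],
                                R = R, I = I)
    selected <- c(selected, pick)
    remaining <- remaining[-pick_pos]
  }
  structure(list(selected = selected,
                 score_trace = do.call(rbind, trace),
                 similarity = S, G = G, weights = w),
            class = "selection_result")
}

#' Grid search over the selection weights
#'
#' Evaluates `runner(r, b)` for all 16 combinations of
#' `r, b in {0.1, 0.5, 1, 5}` and returns the maximizing pair (ties broken
#' toward smaller r, then smaller b).
#'
#' @param runner function `(r, b) -> scalar` validation metric (larger is
#'   better)
#' @param grid candidate values for both weights
#' @return a [score_weights()] with the full results table in attribute
#'   `"results"`
#' @export
grid_search_weights <- function(runner, grid = c(0.1, 0.5, 1, 5)) {
  grid <- sort(grid)
  res <- expand.grid(b = grid, r = grid)[, c("r", "b")]  # r varies slowest
  res <- res[order(res$r, res$b), ]
  res$metric <- NA_real_
  for (i in seq_len(nrow(res))) {
    res$metric[i] <- tryCatch(
      as.numeric(runner(res$r[i], res$b[i])),
      error = function(e) stop(sprintf("grid cell (r=%g, b=%g) failed: %s",
                                       res$r[i], res$b[i], conditionMessage(e)),
                               call. = FALSE)
    )
  }
  best <- which.max(res$metric)  # rows ordered by (r, b): first max wins ties
  out <- score_weights(res$r[best], res$b[best])
  attr(out, "results") <- res
  out
}
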