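# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Derive a reproducible child seed below 2^31 from a master seed
#' @noRd
derive_seed <- function(seed, k) {
  ((abs(as.numeric(seed)) %% 1e5) * 10007 + as.numeric(k) * 97 + 13) %% 2147483629 + 1
}

#' Stop with a validation error naming the offending field
#' @noRd
abort_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

#' Row-wise log-sum-exp
#' @noRd
log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Row-wise softmax in log space (stable)
#' @noRd
softmax_rows <- function(M) {
  mx <- apply(M, 1L, max)
  E <- exp(M - mx)
  E / rowSums(E)
}

#' Shannon entropy of each row of a probability matrix (natural log, 0 log 0 = 0)
#' @noRd
row_entropy <- function(P) {
  PL <- P * log(P)
  PL[P <= 0] <- 0
  -rowSums(PL)
}

#' Check a numeric matrix for non-finite entries
#' @noRd
assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

as_matrix_features <- function(x) {
  if (inherits(x, "al_dataset")) return(x$features)
  if (is.data.frame(x)) return(as.matrix(x))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

#' Best-permutation clustering accuracy
#'
#' Fraction of samples whose cluster assignment matches the ground truth
#' under the best one-to-one relabeling of clusters. Used to evaluate
#' unsupervised cluster recovery. Exhaustive over permutations for up to 8
#' clusters; greedy matching beyond that.
#'
#' @param assignment integer vector of cluster ids (any coding)
#' @param truth integer vector of ground-truth ids, same length
#' @return a single number in \[0, 1\]
#' @export
cluster_accuracy <- function(assignment, truth) {
  stopifnot(length(assignment) == length(truth))
  a <- as.integer(factor(assignment))
  t <- as.integer(factor(truth))
  K <- max(a, t)
  conf <- matrix(0L, K, K)
  for (i in seq_along(a)) conf[a[i], t[i]] <- conf[a[i], t[i]] + 1L
  if (K <= 8L) {
    perms <- all_permutations(K)
    best <- 0L
    for (p in perms) {
      s <- sum(conf[cbind(seq_len(K), p)])
      if (s > best) best <- s
    }
  } else {
    # greedy assignment, largest counts first
    best <- 0L
    cf <- conf
    for (step in seq_len(K)) {
      idx <- which(cf == max(cf), arr.ind = TRUE)[1L, ]
      best <- best + cf[idx[1L], idx[2L]]
      cf[idx[1L], ] <- -1L
      cf[, idx[2L]] <- -1L
    }
  }
  best / length(a)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}
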