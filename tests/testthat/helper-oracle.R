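# Independent brute-force oracles, written with explicit loops and no reuse
# of the package's vectorized code paths. These are the reference against
# which the selection machinery is checked.

oracle_rbf_sim <- function(E, sigma) {
  n <- nrow(E)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-sum((E[i, ] - E[j, ])^2) / (2 * sigma^2))
    }
  }
  S
}

oracle_representativeness <- function(S, cluster_ids) {
  n <- nrow(S)
  G <- numeric(n)
  for (i in seq_len(n)) {
    mates <- setdiff(which(cluster_ids == cluster_ids[i]), i)
    G[i] <- if (length(mates) == 0L) 0 else {
      acc <- 0
      for (j in mates) acc <- acc + S[i, j]
      acc / length(mates)
    }
  }
  G
}

# Step-by-step greedy selection: at every step, every remaining candidate's
# diversity is recomputed against the current selection and the largest
# composite score wins (first/lowest index on ties).
oracle_greedy <- function(H, E, cluster_ids, B, r, b, sigma) {
  n <- nrow(E)
  S <- oracle_rbf_sim(E, sigma)
  G <- oracle_representativeness(S, cluster_ids)
  selected <- integer(0)
  while (length(selected) < min(B, n)) {
    best <- -Inf
    best_i <- NA_integer_
    for (i in seq_len(n)) {
      if (i %in% selected) next
      R <- if (length(selected) == 0L) 0 else {
        acc <- 0
        for (s in selected) acc <- acc + S[i, s]
        -acc / length(selected)
      }
      I <- H[i] + r * G[i] + b * R
      if (I > best) {
        best <- I
        best_i <- i
      }
    }
    selected <- c(selected, best_i)
  }
  selected
}

# One-vs-rest AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  acc <- 0
  for (i in pos) {
    for (j in neg) {
      acc <- acc + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  acc / (length(pos) * length(neg))
}
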