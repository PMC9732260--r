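#' Configuration for a pool-based active-learning experiment
#'
#' Orchestrates the full protocol: stratified train/test split, random
#' initialization of labeled/unlabeled pools, per-round classifier training
#' and evaluation, query selection by the configured strategy, label
#' revelation, and multi-seed averaging.
#'
#' @param initial_labeled_fraction fraction of the training pool labeled at
#'   round 0 (ignored when `initial_labeled_count` is given)
#' @param initial_labeled_count absolute initial labeled-pool size
#' @param rounds number of query rounds
#' @param budget_B samples queried per round
#' @param strategy `"composite"` (entropy + representativeness + diversity
#'   in the latent space), `"max_entropy"`, or `"random"`
#' @param weights a [score_weights()], or the string `"grid"` to resolve the
#'   weights by grid search before the run
#' @param n_repeats independent repeats (pools re-initialized each time)
#' @param seed master seed; every repeat derives its own seeds from it
#' @param vade_config a [vade_config()]
#' @param task_config a [task_config()]
#' @param sim_config a [similarity_config()]
#' @param test_fraction held-out stratified test fraction
#' @param vade_retrain retrain the embedding model every round (default:
#'   train once per repeat on all training data, since it is unsupervised
#'   and the pool contents do not change)
#' @param normalize_scores divide the entropy term by `log C` in the
#'   composite score
#' @return an object of class `al_config`
#' @export
al_config <- function(initial_labeled_fraction = 0.1,
                      initial_labeled_count = NULL,
                      rounds = 5L,
                      budget_B = 100L,
                      strategy = c("composite", "max_entropy", "random"),
                      weights = score_weights(1, 1),
                      n_repeats = 5L,
                      seed = 1L,
                      vade_config = embedal::vade_config(),
                      task_config = embedal::task_config(),
                      sim_config = embedal::similarity_config(),
                      test_fraction = 0.2,
                      vade_retrain = FALSE,
                      normalize_scores = FALSE) {
  strategy <- match.arg(strategy)
  if (!is.null(initial_labeled_count) && initial_labeled_count < 1)
    abort_field("initial_labeled_count", "must be >= 1")
  if (is.null(initial_labeled_count) &&
      (initial_labeled_fraction <= 0 || initial_labeled_fraction >= 1))
    abort_field("initial_labeled_fraction", "must lie in (0, 1)")
  if (rounds < 0) abort_field("rounds", "must be >= 0")
  if (budget_B < 1) abort_field("budget_B", "must be >= 1")
  if (n_repeats < 1) abort_field("n_repeats", "must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    abort_field("test_fraction", "must lie in (0, 1)")
  if (!identical(weights, "grid") && !inherits(weights, "score_weights"))
    abort_field("weights", "must be score_weights() or \"grid\"")
  structure(list(
    initial_labeled_fraction = initial_labeled_fraction,
    initial_labeled_count = initial_labeled_count,
    rounds = as.integer(rounds), budget_B = as.integer(budget_B),
    strategy = strategy, weights = weights,
    n_repeats = as.integer(n_repeats), seed = as.integer(seed),
    vade_config = vade_config, task_config = task_config,
    sim_config = sim_config, test_fraction = test_fraction,
    vade_retrain = vade_retrain, normalize_scores = normalize_scores
  ), class = "al_config")
}

#' Initialize labeled/unlabeled pools
#'
#' Uniform random draw without replacement of the initial labeled set from
#' the training indices; the remainder forms the unlabeled pool.
#'
#' @param n_train number of training samples (or an `al_dataset`, in which
#'   case all its rows form the pool)
#' @param config an [al_config()]
#' @param seed seed for the draw
#' @return object of class `pool_state`: `labeled_indices`,
#'   `unlabeled_indices` (disjoint, union = all indices)
#' @export
initialize_pools <- function(n_train, config, seed = config$seed) {
  if (inherits(n_train, "al_dataset")) n_train <- nrow(n_train$features)
  n0 <- config$initial_labeled_count %||%
    max(1L, round(config$initial_labeled_fraction * n_train))
  n0 <- min(as.integer(n0), n_train)
  if (n0 == 0L) stop("initial labeled pool would be empty", call. = FALSE)
  labeled <- with_seed(seed, sort(sample.int(n_train, n0)))
  structure(list(labeled_indices = labeled,
                 unlabeled_indices = setdiff(seq_len(n_train), labeled)),
            class = "pool_state")
}

check_pool_classes <- function(pool, labels, n_classes) {
  present <- length(unique(labels[pool$labeled_indices]))
  if (present < n_classes)
    warning(sprintf("initial labeled pool covers %d of %d classes", present, n_classes),
            call. = FALSE)
  invisible(pool)
}

#' Random query selection (baseline)
#'
#' Uniform draw without replacement from the unlabeled pool.
#'
#' @param pool a `pool_state`
#' @param B budget
#' @param seed seed for the draw
#' @return integer vector of selected sample indices (size `min(B, |D_U|)`)
#' @export
select_random <- function(pool, B, seed) {
  U <- pool$unlabeled_indices
  if (length(U) == 0L) return(integer(0))
  k <- min(B, length(U))
  with_seed(seed, U[sample.int(length(U), k)])
}

#' Maximum-entropy query selection (baseline)
#'
#' Picks the `B` unlabeled samples with the highest predictive entropy
#' (ties toward the lowest sample index). Identical to [greedy_select()]
#' with both weights zero.
#'
#' @param pred a `predictive_distribution` whose rows follow
#'   `pool$unlabeled_indices`
#' @param pool a `pool_state`
#' @param B budget
#' @return integer vector of selected sample indices, entropy-descending
#' @export
select_max_entropy <- function(pred, pool, B) {
  U <- pool$unlabeled_indices
  H <- uncertainty_score(pred)
  if (length(H) != length(U))
    stop("predictions must cover the unlabeled pool", call. = FALSE)
  k <- min(B, length(U))
  ord <- order(-H, U)  # descending entropy, ties toward lowest index
  U[ord[seq_len(k)]]
}

#' Classification metrics: accuracy, micro-F1, average one-vs-rest AUC
#'
#' Accuracy is the fraction of argmax-correct rows (ties toward the lowest
#' class); micro-F1 pools true/false positives over classes (for
#' single-label multiclass it equals accuracy); AVG-AUC is the unweighted
#' mean over classes of the one-vs-rest area under the ROC curve of the
#' class-probability column, computed by the rank (Mann-Whitney) statistic.
#' Classes absent from the labels are skipped with a message.
#'
#' @param predictions a `predictive_distribution` or probability matrix
#' @param labels integer labels in `0 .. C-1`
#' @return list with `accuracy`, `micro_f1`, `avg_auc`
#' @export
evaluate_predictions <- function(predictions, labels) {
  P <- if (inherits(predictions, "predictive_distribution")) predictions$probabilities else as.matrix(predictions)
  labels <- as.integer(labels)
  stopifnot(nrow(P) == length(labels))
  C <- ncol(P)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: test labels contain a single class", call. = FALSE)
  yhat <- max.col(P, ties.method = "first") - 1L
  acc <- mean(yhat == labels)
  tp <- fp <- fn <- 0
  for (c0 in seq_len(C) - 1L) {
    tp <- tp + sum(yhat == c0 & labels == c0)
    fp <- fp + sum(yhat == c0 & labels != c0)
    fn <- fn + sum(yhat != c0 & labels == c0)
  }
  micro_f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  aucs <- c()
  for (c0 in seq_len(C) - 1L) {
    pos <- labels == c0
    if (!any(pos)) {
      message(sprintf("class %d absent from test labels; skipped in AVG-AUC", c0))
      next
    }
    aucs <- c(aucs, rank_auc(P[, c0 + 1L], pos))
  }
  list(accuracy = acc, micro_f1 = micro_f1, avg_auc = mean(aucs))
}

# One-vs-rest AUC via the rank statistic; midranks handle score ties.
rank_auc <- function(score, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified train/test split
#'
#' @param labels integer labels
#' @param test_fraction fraction held out per class
#' @param seed seed
#' @return list with integer index vectors `train` and `test`
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  with_seed(seed, {
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- max(1L, round(test_fraction * length(idx)))
      test <- c(test, idx[sample.int(length(idx), min(k, length(idx)))])
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

# ---- the experiment engine --------------------------------------------------

# One repeat of the AL protocol for one strategy, starting from shared
# pools/model. Returns per-round records and (optionally) the pool history.
run_single_repeat <- function(Xtr, ytr, Xte, yte, vmodel, pool0, strategy,
                              config, repeat_seed, n_classes,
                              keep_pools = FALSE) {
  pool <- pool0
  weights <- if (inherits(config$weights, "score_weights")) config$weights else score_weights(1, 1)
  records <- vector("list", config$rounds + 1L)
  pools <- if (keep_pools) vector("list", config$rounds + 1L)
  for (round in 0:config$rounds) {
    tcfg <- config$task_config
    tcfg$seed <- derive_seed(repeat_seed, round)
    clf <- train_classifier(vmodel, Xtr[pool$labeled_indices, , drop = FALSE],
                            ytr[pool$labeled_indices], tcfg,
                            n_classes = n_classes)
    pred_te <- with_seed(derive_seed(repeat_seed, 1000 + round),
                         predict_classifier(vmodel, clf, Xte))
    m <- evaluate_predictions(pred_te, yte)
    records[[round + 1L]] <- data.frame(
      strategy = strategy, repeat_seed = repeat_seed, round = round,
      labeled_size = length(pool$labeled_indices),
      accuracy = m$accuracy, micro_f1 = m$micro_f1, avg_auc = m$avg_auc)
    if (keep_pools) pools[[round + 1L]] <- pool
    if (round == config$rounds) break
    U <- pool$unlabeled_indices
    if (length(U) == 0L) {
      message(sprintf("unlabeled pool exhausted at round %d", round))
      break
    }
    B <- config$budget_B
    if (B > length(U)) {
      message(sprintf("budget truncated to %d at round %d", length(U), round))
      B <- length(U)
    }
    picked <- if (strategy == "random") {
      select_random(pool, B, derive_seed(repeat_seed, 2000 + round))
    } else {
      pred_u <- with_seed(derive_seed(repeat_seed, 3000 + round),
                          predict_classifier(vmodel, clf, Xtr[U, , drop = FALSE]))
      if (strategy == "max_entropy") {
        select_max_entropy(pred_u, pool, B)
      } else {
        emb <- vade_encode(vmodel, Xtr[U, , drop = FALSE], L = 1L,
                           epsilon = array(0, c(1L, length(U), vmodel$config$latent_dim)))$mean
        cl_ids <- cluster_posterior(vmodel, Xtr[U, , drop = FALSE])$hard_assignment
        sel <- greedy_select(uncertainty_score(pred_u), emb, cl_ids, B,
                             w = weights, sim_config = config$sim_config,
                             normalize = config$normalize_scores,
                             n_classes = n_classes)
        U[sel$selected]
      }
    }
    pool <- structure(list(
      labeled_indices = sort(c(pool$labeled_indices, picked)),
      unlabeled_indices = setdiff(pool$unlabeled_indices, picked)
    ), class = "pool_state")
  }
  records <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  if (keep_pools) list(records = records, pools = pools) else list(records = records)
}

#' Run a full active-learning experiment
#'
#' For each of `n_repeats` derived seeds: split the data (stratified,
#' shared across repeats), initialize pools, train the embedding model on
#' all training data (it is unsupervised), then alternate task-learner
#' training / test-set evaluation / query selection for `rounds` rounds.
#'
#' @param dataset an `al_dataset`
#' @param config an [al_config()]
#' @param keep_pools keep the per-round pool states (for invariant checks)
#' @return list of class `al_result`: `records` (one row per repeat x
#'   round), `summary` (per-round mean and sd of each metric), and `config`
#' @export
run_experiment <- function(dataset, config, keep_pools = FALSE) {
  stopifnot(inherits(dataset, "al_dataset"), inherits(config, "al_config"))
  if (identical(config$weights, "grid")) {
    config$weights <- resolve_grid_weights(dataset, config)
  }
  sp <- train_test_split(dataset$labels, config$test_fraction, config$seed)
  n_classes <- max(dataset$labels) + 1L
  Xtr <- dataset$features[sp$train, , drop = FALSE]
  ytr <- dataset$labels[sp$train]
  Xte <- dataset$features[sp$test, , drop = FALSE]
  yte <- dataset$labels[sp$test]
  all_records <- list()
  all_pools <- list()
  for (i in seq_len(config$n_repeats)) {
    repeat_seed <- derive_seed(config$seed, i)
    pool0 <- initialize_pools(nrow(Xtr), config, seed = repeat_seed)
    check_pool_classes(pool0, ytr, n_classes)
    if (config$rounds > 0L && config$budget_B * config$rounds > length(pool0$unlabeled_indices))
      warning("budget_B * rounds exceeds the unlabeled pool; final rounds will be truncated",
              call. = FALSE)
    vcfg <- config$vade_config
    vcfg$n_clusters <- vcfg$n_clusters %||% n_classes
    vcfg$seed <- as.integer(derive_seed(repeat_seed, 77))
    vmodel <- vade_train(Xtr, vcfg)
    rr <- run_single_repeat(Xtr, ytr, Xte, yte, vmodel, pool0,
                            config$strategy, config, repeat_seed, n_classes,
                            keep_pools = keep_pools)
    all_records[[i]] <- rr$records
    if (keep_pools) all_pools[[i]] <- rr$pools
  }
  records <- do.call(rbind, all_records)
  out <- list(records = records, summary = summarize_records(records),
              config = config)
  if (keep_pools) out$pools <- all_pools
  structure(out, class = "al_result")
}

#' Compare several strategies under shared seeds
#'
#' Runs each strategy from identical initial pools and an identical
#' per-repeat embedding model, so round-0 metrics coincide across
#' strategies and differences are attributable to the query strategy alone.
#'
#' @param dataset an `al_dataset`
#' @param config an [al_config()] (its `strategy` field is ignored)
#' @param strategies character vector of strategies to run
#' @return an `al_result` whose records and summary cover all strategies
#' @export
compare_strategies <- function(dataset, config,
                               strategies = c("random", "max_entropy", "composite")) {
  stopifnot(inherits(dataset, "al_dataset"), inherits(config, "al_config"))
  sp <- train_test_split(dataset$labels, config$test_fraction, config$seed)
  n_classes <- max(dataset$labels) + 1L
  Xtr <- dataset$features[sp$train, , drop = FALSE]
  ytr <- dataset$labels[sp$train]
  Xte <- dataset$features[sp$test, , drop = FALSE]
  yte <- dataset$labels[sp$test]
  all_records <- list()
  for (i in seq_len(config$n_repeats)) {
    repeat_seed <- derive_seed(config$seed, i)
    pool0 <- initialize_pools(nrow(Xtr), config, seed = repeat_seed)
    vcfg <- config$vade_config
    vcfg$n_clusters <- vcfg$n_clusters %||% n_classes
    vcfg$seed <- as.integer(derive_seed(repeat_seed, 77))
    vmodel <- vade_train(Xtr, vcfg)
    for (s in strategies) {
      rr <- run_single_repeat(Xtr, ytr, Xte, yte, vmodel, pool0, s, config,
                              repeat_seed, n_classes)
      all_records[[length(all_records) + 1L]] <- rr$records
    }
  }
  records <- do.call(rbind, all_records)
  structure(list(records = records, summary = summarize_records(records),
                 config = config),
            class = "al_result")
}

summarize_records <- function(records) {
  grp <- split(records, list(records$strategy, records$round), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    strategy = g$strategy[1L], round = g$round[1L], n = nrow(g),
    labeled_size = mean(g$labeled_size),
    accuracy_mean = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
    micro_f1_mean = mean(g$micro_f1), micro_f1_sd = stats::sd(g$micro_f1),
    avg_auc_mean = mean(g$avg_auc), avg_auc_sd = stats::sd(g$avg_auc)
  )))
  out <- out[order(out$strategy, out$round), ]
  rownames(out) <- NULL
  out
}

resolve_grid_weights <- function(dataset, config) {
  base <- config
  base$weights <- NULL
  runner <- function(r, b) {
    cfg <- base
    cfg$weights <- score_weights(r, b)
    cfg$strategy <- "composite"
    cfg$n_repeats <- 1L
    res <- run_experiment(dataset, cfg)
    final <- res$records[res$records$round == max(res$records$round), ]
    mean(final$accuracy)
  }
  grid_search_weights(runner)
}

#' @export
print.al_result <- function(x, ...) {
  cat("<al_result>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write experiment reports
#'
#' Emits `records.csv` (long format: strategy, repeat_seed, round,
#' labeled_size, accuracy, micro_f1, avg_auc), `summary.csv` (per-strategy,
#' per-round means and standard deviations) and `config.json` (a run
#' snapshot for provenance).
#'
#' @param result an `al_result` (or a records data.frame)
#' @param path output directory (created if missing)
#' @return character vector of the files written, invisibly
#' @export
write_report <- function(result, path) {
  records <- if (inherits(result, "al_result")) result$records else result
  summary <- if (inherits(result, "al_result")) result$summary else summarize_records(records)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(path, "records.csv")
  f2 <- file.path(path, "summary.csv")
  f3 <- file.path(path, "config.json")
  data.table::fwrite(records, f1)
  data.table::fwrite(summary, f2)
  cfg <- if (inherits(result, "al_result")) result$config else NULL
  jsonlite::write_json(config_to_list(cfg), f3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(f1, f2, f3))
}

config_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) return(lapply(unclass(x), config_to_list))
  x
}
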