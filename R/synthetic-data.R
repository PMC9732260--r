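#' Specification of a synthetic class-structured dataset
#'
#' Describes a population with Gaussian-mixture latent structure: each class
#' owns one or more latent clusters whose means sit at the vertices of a
#' scaled simplex (mutual distance `cluster_separation` in units of the
#' within-cluster standard deviation), mapped to an observation space either
#' by a fixed full-rank linear map plus isotropic noise or by rendering each
#' latent point as a small grayscale blob image. This mirrors the generative
#' assumptions of a Gaussian-mixture-prior variational autoencoder, so
#' cluster recovery is testable against known ground truth.
#'
#' @param n_samples number of samples to draw (>= `n_classes`)
#' @param n_classes number of classes C (labels are `0 .. C-1`)
#' @param clusters_per_class latent clusters owned by each class
#' @param latent_dim dimension of the latent space
#' @param observation_dim dimension of the observed feature vectors; for
#'   `observation_map = "blob_image"` it must be a perfect square
#' @param cluster_separation distance between latent cluster means, in units
#'   of `within_cluster_sd`
#' @param within_cluster_sd isotropic latent standard deviation within a cluster
#' @param observation_map `"linear"` or `"blob_image"`
#' @param observation_noise_sd sd of isotropic Gaussian observation noise
#' @param label_noise_rate fraction of labels reassigned uniformly at random
#'   over the other C-1 classes
#' @param class_proportions simplex vector of length `n_classes` (sums to 1)
#' @param seed integer seed; all generator randomness derives from it
#' @return an object of class `synthetic_spec`
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_samples,
                           n_classes,
                           clusters_per_class = 1L,
                           latent_dim = 2L,
                           observation_dim = 16L,
                           cluster_separation = 4,
                           within_cluster_sd = 1,
                           observation_map = c("linear", "blob_image"),
                           observation_noise_sd = 0.05,
                           label_noise_rate = 0,
                           class_proportions = NULL,
                           seed = 1L) {
  observation_map <- match.arg(observation_map)
  if (length(n_samples) != 1L || n_samples < 1) abort_field("n_samples", "must be a positive count")
  if (length(n_classes) != 1L || n_classes < 1) abort_field("n_classes", "must be a positive count")
  if (n_samples < n_classes) abort_field("n_samples", "must be >= n_classes")
  if (clusters_per_class < 1) abort_field("clusters_per_class", "must be >= 1")
  if (latent_dim < 1) abort_field("latent_dim", "must be >= 1")
  if (observation_map == "linear" && observation_dim < latent_dim)
    abort_field("observation_dim", "must be >= latent_dim for the linear map")
  if (observation_map == "blob_image") {
    side <- sqrt(observation_dim)
    if (side != floor(side)) abort_field("observation_dim", "must be a perfect square for blob_image")
  }
  if (cluster_separation < 0) abort_field("cluster_separation", "must be nonnegative")
  if (within_cluster_sd <= 0) abort_field("within_cluster_sd", "must be positive")
  if (observation_noise_sd < 0) abort_field("observation_noise_sd", "must be nonnegative")
  if (label_noise_rate < 0 || label_noise_rate > 1) abort_field("label_noise_rate", "must lie in [0, 1]")
  if (is.null(class_proportions)) class_proportions <- rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes) abort_field("class_proportions", "length must equal n_classes")
  if (any(class_proportions < 0)) abort_field("class_proportions", "entries must be nonnegative")
  if (abs(sum(class_proportions) - 1) > 1e-9) abort_field("class_proportions", "must sum to 1 within 1e-9")
  structure(list(
    n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
    clusters_per_class = as.integer(clusters_per_class),
    latent_dim = as.integer(latent_dim), observation_dim = as.integer(observation_dim),
    cluster_separation = cluster_separation, within_cluster_sd = within_cluster_sd,
    observation_map = observation_map, observation_noise_sd = observation_noise_sd,
    label_noise_rate = label_noise_rate, class_proportions = class_proportions,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# K mutually equidistant points (unit pairwise distance) embedded in `dim`
# dimensions. Needs dim >= K-1; otherwise callers fall back to an axis grid.
simplex_vertices <- function(K, dim) {
  if (K == 1L) return(matrix(0, 1L, dim))
  V <- diag(K)
  V <- sweep(V, 2L, colMeans(V))
  s <- svd(V)
  P <- s$u[, seq_len(K - 1L), drop = FALSE] %*% diag(s$d[seq_len(K - 1L)], K - 1L)
  P <- P / sqrt(2)  # vertices of identity simplex are sqrt(2) apart
  out <- matrix(0, K, dim)
  out[, seq_len(K - 1L)] <- P
  out
}

cluster_mean_layout <- function(K, latent_dim, separation, sd) {
  d <- separation * sd
  if (latent_dim >= K - 1L && latent_dim > 1L || K == 1L) {
    simplex_vertices(K, latent_dim) * d
  } else {
    # 1-D latent space (or too few dimensions for a simplex): evenly spaced
    # means on the first axis, adjacent pairs `separation` apart.
    M <- matrix(0, K, latent_dim)
    M[, 1L] <- (seq_len(K) - (K + 1) / 2) * d
    M
  }
}

#' Generate a synthetic dataset from a specification
#'
#' Draws classes from `class_proportions`, picks a latent cluster uniformly
#' among the class's clusters, samples latent points from isotropic
#' Gaussians at deterministic simplex-vertex means, maps them to observation
#' space, and optionally flips a fraction of labels. Fully determined by
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()]
#' @return an object of class `al_dataset` with elements
#'   \describe{
#'     \item{features}{`n_samples x observation_dim` numeric matrix}
#'     \item{labels}{integer vector, values in `0 .. C-1`}
#'     \item{true_cluster_ids}{integer vector of ground-truth cluster ids (0-based)}
#'     \item{latents}{the latent points (ground truth, for evaluation only)}
#'     \item{latent_means}{cluster-mean matrix used for generation}
#'     \item{cluster_class_map}{integer vector: class of each cluster id}
#'     \item{observation_matrix}{the linear map (linear mode only)}
#'     \item{spec}{the generating spec}
#'   }
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_classes
  K <- C * spec$clusters_per_class
  with_seed(spec$seed, {
    means <- cluster_mean_layout(K, spec$latent_dim, spec$cluster_separation,
                                 spec$within_cluster_sd)
    cluster_class <- (seq_len(K) - 1L) %/% spec$clusters_per_class  # 0-based classes
    A <- NULL
    if (spec$observation_map == "linear") {
      # full-rank map with orthonormal columns: pseudo-inverse recovery is exact
      G <- matrix(stats::rnorm(spec$observation_dim * spec$latent_dim),
                  spec$observation_dim, spec$latent_dim)
      A <- qr.Q(qr(G))[, seq_len(spec$latent_dim), drop = FALSE]
    }
    n <- spec$n_samples
    classes <- sample.int(C, n, replace = TRUE, prob = spec$class_proportions) - 1L
    offset <- classes * spec$clusters_per_class
    pick <- if (spec$clusters_per_class > 1L) sample.int(spec$clusters_per_class, n, replace = TRUE) - 1L else 0L
    clusters <- offset + pick  # 0-based cluster ids
    Z <- means[clusters + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$latent_dim, sd = spec$within_cluster_sd), n, spec$latent_dim)
    if (spec$observation_map == "linear") {
      X <- tcrossprod(Z, A)
      if (spec$observation_noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = spec$observation_noise_sd), nrow(X), ncol(X))
    } else {
      X <- render_blobs(Z, spec$observation_dim, spec$observation_noise_sd)
    }
    labels <- cluster_class[clusters + 1L]
    if (spec$label_noise_rate > 0 && C > 1L) {
      flip <- stats::runif(n) < spec$label_noise_rate
      if (any(flip)) {
        shift <- sample.int(C - 1L, sum(flip), replace = TRUE)
        labels[flip] <- (labels[flip] + shift) %% C
      }
    }
    structure(list(
      features = X,
      labels = as.integer(labels),
      true_cluster_ids = as.integer(clusters),
      latents = Z,
      latent_means = means,
      cluster_class_map = as.integer(cluster_class),
      observation_matrix = A,
      spec = spec
    ), class = "al_dataset")
  })
}

# Render each latent point as a flattened side x side grayscale image with a
# single Gaussian blob. The first two latent coordinates set the blob center
# (through a probit squashing into the central region), the third, when
# present, its size. Values clipped to [0, 1].
render_blobs <- function(Z, observation_dim, noise_sd) {
  side <- as.integer(sqrt(observation_dim))
  n <- nrow(Z)
  J <- ncol(Z)
  cx <- 0.15 + 0.7 * stats::pnorm(Z[, 1L] / 4)
  cy <- if (J >= 2L) 0.15 + 0.7 * stats::pnorm(Z[, 2L] / 4) else rep(0.5, n)
  sz <- if (J >= 3L) 0.05 + 0.15 * stats::pnorm(Z[, 3L] / 4) else rep(0.12, n)
  gx <- (seq_len(side) - 0.5) / side
  X <- matrix(0, n, observation_dim)
  for (i in seq_len(n)) {
    # row-major flattening: pixel (r, c) -> (r - 1) * side + c
    img <- exp(-(outer((gx - cy[i])^2, (gx - cx[i])^2, "+")) / (2 * sz[i]^2))
    X[i, ] <- as.vector(t(img))
  }
  if (noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), n, observation_dim)
  pmin(pmax(X, 0), 1)
}

#' Write a dataset to a directory
#'
#' Stores `features.csv` (dense numeric matrix, no header, full precision),
#' `labels.csv` (`sample_id,label` with header) and, when ground-truth
#' cluster ids are present, `clusters.csv` (`sample_id,cluster`).
#'
#' @param ds an `al_dataset`
#' @param directory output directory (created if missing)
#' @return the directory path, invisibly
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "al_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(ds$features),
                     file.path(directory, "features.csv"),
                     col.names = FALSE)
  data.table::fwrite(data.table::data.table(sample_id = seq_len(nrow(ds$features)),
                                            label = ds$labels),
                     file.path(directory, "labels.csv"))
  if (!is.null(ds$true_cluster_ids)) {
    data.table::fwrite(data.table::data.table(sample_id = seq_len(nrow(ds$features)),
                                              cluster = ds$true_cluster_ids),
                       file.path(directory, "clusters.csv"))
  }
  invisible(directory)
}

#' Read a dataset from a directory written by [write_dataset()]
#'
#' @param directory directory containing `features.csv` and `labels.csv`
#' @return an `al_dataset` (without a generating spec)
#' @export
read_dataset <- function(directory) {
  fpath <- file.path(directory, "features.csv")
  lpath <- file.path(directory, "labels.csv")
  if (!file.exists(fpath)) stop("format error: missing file 'features.csv'", call. = FALSE)
  if (!file.exists(lpath)) stop("format error: missing file 'labels.csv'", call. = FALSE)
  feat <- tryCatch(
    as.matrix(data.table::fread(fpath, header = FALSE, fill = FALSE)),
    error = function(e) stop("format error in 'features.csv': ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("format error in 'features.csv': ", conditionMessage(w), call. = FALSE)
  )
  storage.mode(feat) <- "double"
  dimnames(feat) <- NULL
  if (!all(is.finite(feat))) stop("format error in 'features.csv': non-finite entries", call. = FALSE)
  lab <- data.table::fread(lpath)
  if (!all(c("sample_id", "label") %in% names(lab)))
    stop("format error in 'labels.csv': expected header sample_id,label", call. = FALSE)
  if (nrow(lab) != nrow(feat))
    stop("format error in 'labels.csv': row count does not match 'features.csv'", call. = FALSE)
  lab <- lab[order(lab$sample_id), ]
  clusters <- NULL
  cpath <- file.path(directory, "clusters.csv")
  if (file.exists(cpath)) {
    cl <- data.table::fread(cpath)
    if (!all(c("sample_id", "cluster") %in% names(cl)))
      stop("format error in 'clusters.csv': expected header sample_id,cluster", call. = FALSE)
    if (nrow(cl) != nrow(feat))
      stop("format error in 'clusters.csv': row count does not match 'features.csv'", call. = FALSE)
    cl <- cl[order(cl$sample_id), ]
    clusters <- as.integer(cl$cluster)
  }
  structure(list(features = feat, labels = as.integer(lab$label),
                 true_cluster_ids = clusters, spec = NULL),
            class = "al_dataset")
}

#' @export
print.al_dataset <- function(x, ...) {
  cat(sprintf("<al_dataset> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), length(unique(x$labels))))
  invisible(x)
}

# ---- image folder loading ---------------------------------------------------

# Minimal netpbm grayscale reader (P2 ASCII / P5 binary). The offline R
# environment has no PNG codec, so PGM is the supported on-disk image format.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  # tokenize header (magic, width, height, maxval), honoring '#' comments
  txt <- rawToChar(raw_all[seq_len(min(length(raw_all), 512L))])
  toks <- character(0)
  pos <- 1L
  nchars <- nchar(txt)
  consumed <- 0L
  while (length(toks) < 4L && pos <= nchars) {
    ch <- substr(txt, pos, pos)
    if (ch == "#") {
      while (pos <= nchars && substr(txt, pos, pos) != "\n") pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= nchars && !grepl("[[:space:]]", substr(txt, pos, pos))) pos <- pos + 1L
      toks <- c(toks, substr(txt, start, pos - 1L))
    }
  }
  if (length(toks) < 4L || !(toks[1L] %in% c("P2", "P5")))
    stop(sprintf("'%s' is not a P2/P5 PGM image", path), call. = FALSE)
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L]); maxval <- as.integer(toks[4L])
  if (toks[1L] == "P2") {
    body <- sub("P2", "", rawToChar(raw_all), fixed = TRUE)
    vals <- scan(text = body, what = integer(), comment.char = "#", quiet = TRUE)
    vals <- vals[-(1:3)]  # width, height, maxval
  } else {
    # binary data starts right after the single whitespace ending the header
    vals <- as.integer(raw_all[(length(raw_all) - w * h + 1L):length(raw_all)])
  }
  if (length(vals) != w * h)
    stop(sprintf("'%s': expected %d pixels, found %d", path, w * h, length(vals)), call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

# Bilinear resize of a [0,1] grayscale matrix to side x side.
resize_gray <- function(img, side) {
  h <- nrow(img); w <- ncol(img)
  if (h == side && w == side) return(img)
  yi <- (seq_len(side) - 0.5) * h / side + 0.5
  xi <- (seq_len(side) - 0.5) * w / side + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xi), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  out <- matrix(0, side, side)
  for (r in seq_len(side)) {
    row0 <- img[y0[r], ] * (1 - fy[r]) + img[y1[r], ] * fy[r]
    out[r, ] <- row0[x0] * (1 - fx) + row0[x1] * fx
  }
  out
}

#' Write a grayscale matrix as an ASCII PGM image
#'
#' Convenience for building small image fixtures; values in `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`
#' @param path output file path
#' @param maxval maximum gray value written
#' @return `path`, invisibly
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Load a folder of grayscale images as a dataset
#'
#' Each image listed in the label table is converted to grayscale intensities
#' in `[0, 1]`, resized to `side x side` (bilinear) and flattened row-wise.
#' Rows are ordered by sorted file name. Images must be PGM (P2/P5); the
#' offline environment provides no PNG codec.
#'
#' @param directory folder containing the image files
#' @param label_table path to a CSV with columns `file,label`
#' @param side target image side length
#' @return an `al_dataset` with `side^2` feature columns
#' @export
load_image_folder <- function(directory, label_table, side) {
  tab <- data.table::fread(label_table)
  if (!all(c("file", "label") %in% names(tab)))
    stop("format error in label table: expected header file,label", call. = FALSE)
  tab <- tab[order(tab$file), ]
  paths <- file.path(directory, tab$file)
  missing <- !file.exists(paths)
  if (any(missing))
    stop(sprintf("image file listed in label table but absent on disk: '%s'",
                 tab$file[which(missing)[1L]]), call. = FALSE)
  X <- matrix(0, nrow(tab), side * side)
  for (i in seq_len(nrow(tab))) {
    img <- resize_gray(read_pgm(paths[i]), side)
    X[i, ] <- as.vector(t(img))
  }
  structure(list(features = X, labels = as.integer(tab$label),
                 true_cluster_ids = NULL, spec = NULL),
            class = "al_dataset")
}
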