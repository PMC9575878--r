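#' Simulate imbalanced binary-classification data with known informative features
#'
#' Generates one Gaussian cluster per class. A chosen number of informative
#' features carry a class-dependent mean shift; the remaining features are
#' standard-normal noise independent of the label. No redundant
#' (linear-combination) or repeated features are created.
#'
#' The informative block is built in a latent space where the two class
#' centroids sit at `-delta` and `+delta` on every axis with
#' `delta = class_sep / sqrt(n_informative)`, and is then passed through a
#' random full-rank linear map whose columns are scaled to unit norm. Two
#' consequences, both deliberate:
#'
#' * the Mahalanobis distance between the classes is exactly `2 * class_sep`
#'   whatever `n_informative` is (a full-rank map preserves it), so
#'   `class_sep` is the overall separation scale and individual features get
#'   weaker as more of them share the signal — the sequential F1 grid climbs
#'   gradually until the informative set is exhausted;
#' * the informative features are mutually correlated with several
#'   high-variance directions, the covariance structure that makes
#'   principal-component loadings informative about which features matter.
#'
#' The map is full rank, so no feature is a redundant (linear-combination)
#' copy of the others and none is repeated; noise features are independent
#' standard normals.
#'
#' Class counts are deterministic: the majority count is
#' `round(n_samples * class_weights[1])` and the minority gets the remainder.
#' Feature columns are randomly permuted so informative features are not
#' always first; `informative` in the returned object records their positions.
#'
#' @param n_samples Number of samples (rows).
#' @param n_features Total number of features.
#' @param n_informative Number of features carrying class signal
#'   (`0 <= n_informative <= n_features`).
#' @param class_weights Length-2 vector of class proportions
#'   (majority class 0 first), summing to 1. Default balanced.
#' @param class_sep Positive separation scale: half the Euclidean distance
#'   between the two class centroids. Default 1.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An [fs_data] object with the `informative` mask set.
#' @export
#' @examples
#' d <- simulate_binary_data(200, 10, 3, class_weights = c(0.9, 0.1), seed = 1)
#' table(d$y)
#' which(d$informative)
simulate_binary_data <- function(n_samples, n_features, n_informative,
                                 class_weights = c(0.5, 0.5), class_sep = 1,
                                 seed = NULL) {
  stopifnot(n_samples >= 2, n_features >= 1)
  if (n_informative < 0 || n_informative > n_features) {
    stop("n_informative must lie in [0, n_features]")
  }
  if (length(class_weights) != 2L || any(class_weights <= 0) ||
      abs(sum(class_weights) - 1) > 1e-8) {
    stop("class_weights must be two positive proportions summing to 1")
  }
  if (class_sep <= 0) stop("class_sep must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_major <- round(n_samples * class_weights[1])
  n_minor <- n_samples - n_major
  if (n_major < 1 || n_minor < 1) stop("class_weights leave a class empty")
  y <- c(rep(0L, n_major), rep(1L, n_minor))

  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  if (n_informative > 0) {
    k <- n_informative
    delta <- class_sep / sqrt(k)
    shift <- ifelse(y == 1L, delta, -delta)
    mix <- matrix(stats::runif(k * k, -1, 1), k, k)
    mix <- sweep(mix, 2, sqrt(colSums(mix^2)), "/")  # unit within-class variance
    x[, seq_len(k)] <- (x[, seq_len(k), drop = FALSE] + shift) %*% mix
  }

  perm <- sample.int(n_features)          # informative columns land anywhere
  x <- x[, perm, drop = FALSE]
  informative <- logical(n_features)
  if (n_informative > 0) informative[match(seq_len(n_informative), perm)] <- TRUE

  rows <- sample.int(n_samples)           # interleave the class blocks
  fs_data(x[rows, , drop = FALSE], y[rows],
          feature_names = paste0("f", seq_len(n_features)),
          informative = informative)
}

#' Stratified train/test split
#'
#' Partitions an [fs_data] object into disjoint training and test sets. With
#' `stratify = TRUE` (the default) the per-class test counts are
#' `round(n_class * test_fraction)`, so the class imbalance is the same in
#' both parts up to rounding.
#'
#' @param data An [fs_data] object.
#' @param test_fraction Proportion of rows assigned to the test set,
#'   in (0, 1). Default 0.25.
#' @param stratify Preserve per-class proportions? Default `TRUE`.
#' @param seed Optional integer seed.
#'
#' @return A list with [fs_data] elements `train` and `test`, plus integer
#'   vectors `train_idx` and `test_idx` giving the original row indices.
#' @export
#' @examples
#' d <- simulate_binary_data(200, 5, 2, seed = 1)
#' sp <- split_dataset(d, 0.25, seed = 1)
#' nrow(sp$test$x)
split_dataset <- function(data, test_fraction = 0.25, stratify = TRUE,
                          seed = NULL) {
  stopifnot(inherits(data, "fs_data"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$y)
  if (stratify) {
    test_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      rows <- which(data$y == cls)
      k <- round(length(rows) * test_fraction)
      if (k < 1 || k >= length(rows)) {
        stop("class ", cls, " would be absent from one partition")
      }
      test_idx <- c(test_idx, sample(rows, k))
    }
    test_idx <- sort(test_idx)
  } else {
    k <- round(n * test_fraction)
    if (k < 1 || k >= n) stop("test_fraction leaves a partition empty")
    test_idx <- sort(sample.int(n, k))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  for (idx in list(train_idx, test_idx)) {
    if (length(unique(data$y[idx])) < 2L) {
      stop("a class is absent from one partition; adjust test_fraction")
    }
  }
  subset_fs <- function(idx) {
    fs_data(data$x[idx, , drop = FALSE], data$y[idx],
            informative = data$informative)
  }
  list(train = subset_fs(train_idx), test = subset_fs(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
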