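#' Sequential F1 grid over nested PCLFS feature subsets
#'
#' Starting from the highest-ranked feature, features are added one at a time
#' in ranking order; at each size `i` a fresh classifier is fitted on the
#' training rows restricted to the first `i` ordered features and scored on
#' the held-out test rows by minority-class F1. The resulting vector
#' `g = (g_1, ..., g_n)` is the grid the selection rules operate on.
#'
#' @param train,test [fs_data] objects with identical feature columns; the
#'   ranking must have been computed on the training data, and the test rows
#'   must be disjoint from training.
#' @param ranking A [pclfs_rank()] result (defaults to ranking `train$x`).
#' @param classifier Classifier id, see [classifiers].
#' @param seed Optional base seed; fit `i` uses `seed + i` so runs are
#'   reproducible and independent of loop order.
#' @return Object of class `"grid_scores"`: list with `g` (numeric, length
#'   `n`, entries in \[0, 1\]) and `ranking`.
#' @export
grid_scores <- function(train, test, ranking = NULL, classifier = "logit",
                        seed = NULL) {
  stopifnot(inherits(train, "fs_data"), inherits(test, "fs_data"))
  if (is.null(ranking)) ranking <- pclfs_rank(train$x)
  stopifnot(inherits(ranking, "pclfs_ranking"))
  n <- ncol(train$x)
  if (length(ranking$order) != n) stop("ranking does not match feature count")
  g <- numeric(n)
  for (i in seq_len(n)) {
    cols <- ranking$order[seq_len(i)]
    fit <- fit_classifier(train$x[, cols, drop = FALSE], train$y, classifier,
                          seed = if (is.null(seed)) NULL else seed + i)
    pred <- predict_classifier(fit, test$x[, cols, drop = FALSE])
    g[i] <- f1_score(test$y, pred)
  }
  structure(list(g = g, ranking = ranking, classifier = classifier),
            class = "grid_scores")
}

#' PCLFS subset-size choice: smallest argmax of the grid
#'
#' The original PCLFS rule: keep the nested subset with the maximum F1; on
#' ties the smallest size wins.
#'
#' @param g Numeric grid-score vector (or a [grid_scores()] object).
#' @return Integer `n_pclfs` in `1:length(g)`.
#' @export
#' @examples
#' pclfs_select(c(0.2, 0.9, 0.9))
pclfs_select <- function(g) {
  g <- grid_vector(g)
  which.max(g)   # first index attaining the maximum
}

grid_vector <- function(g) {
  if (inherits(g, "grid_scores")) g <- g$g
  g <- as.numeric(g)
  if (length(g) == 0L) stop("empty grid")
  g
}

#' Local maxima of the grid below the PCLFS optimum
#'
#' Candidate stopping points for the extension: indices `j < n_pclfs` whose
#' grid score strictly exceeds both neighbours,
#' `g_j > max(g_{j-1}, g_{j+1})`. At `j = 1` the missing left neighbour is
#' treated as `-Inf`, so an initial peak can qualify. The point at
#' `n_pclfs - 1` is compared against the optimum itself and therefore never
#' qualifies. Plateau points (ties with a neighbour) do not qualify — the
#' comparison is strict.
#'
#' @inheritParams pclfs_select
#' @param n_pclfs The PCLFS choice, from [pclfs_select()].
#' @return Integer vector of candidate indices (possibly empty).
#' @export
#' @examples
#' g <- c(0.60, 0.70, 0.65, 0.72, 0.71, 0.80)
#' local_maxima(g, pclfs_select(g))
local_maxima <- function(g, n_pclfs) {
  g <- grid_vector(g)
  stopifnot(n_pclfs >= 1, n_pclfs <= length(g))
  cand <- integer(0)
  for (j in seq_len(max(n_pclfs - 1L, 0L))) {
    left <- if (j == 1L) -Inf else g[j - 1L]
    if (g[j] > max(left, g[j + 1L])) cand <- c(cand, j)
  }
  cand
}

#' Gradient threshold: tolerable F1 loss per removed feature
#'
#' Spreads the user's maximum tolerable total F1 reduction over the
#' dataset's total feature count: `t = tolerance / n_features`. Note `n` is
#' the total number of features in the dataset, not the PCLFS subset size —
#' the threshold is a per-feature price, fixed by the dataset's
#' dimensionality.
#'
#' @param tolerance Maximum tolerable F1-score reduction (user-defined,
#'   `>= 0`); e.g. 0.05.
#' @param n_features Total number of features in the dataset.
#' @return The threshold `t`.
#' @export
#' @examples
#' gradient_threshold(0.05, 44)   # 0.0011
#' gradient_threshold(0.05, 30)   # 0.0017
gradient_threshold <- function(tolerance, n_features) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  stopifnot(n_features >= 1)
  tolerance / n_features
}

#' Extended subset-size choice by the gradient rule
#'
#' For each local-maximum candidate `j` the gradient of the line connecting
#' it to the optimum is
#' `gradient_j = (g_{n_pclfs} - g_j) / (n_pclfs - j)` — the F1 lost per
#' feature saved. Among candidates with `gradient_j < t` (strictly), the
#' smallest `j` is returned. If no candidate qualifies (including when
#' `n_pclfs = 1`), the PCLFS result stands and `fallback` is `TRUE`.
#'
#' Because `g_{n_pclfs}` is the global maximum, every gradient is
#' non-negative, and the realised loss obeys
#' `g_{n_pclfs} - g_{n_proposed} <= t * (n_pclfs - n_proposed) <= tolerance`.
#'
#' @inheritParams local_maxima
#' @param threshold The per-feature threshold `t` from
#'   [gradient_threshold()].
#' @return List with `n_proposed`, `fallback` (logical), and `candidates`, a
#'   data frame with columns `j`, `g`, `gradient`.
#' @export
#' @examples
#' g <- c(0.60, 0.70, 0.65, 0.72, 0.71, 0.80)
#' ext_select(g, pclfs_select(g), 0.03)
ext_select <- function(g, n_pclfs, threshold) {
  g <- grid_vector(g)
  stopifnot(threshold >= 0)
  cand <- local_maxima(g, n_pclfs)
  candidates <- data.frame(
    j = cand,
    g = g[cand],
    gradient = if (length(cand)) (g[n_pclfs] - g[cand]) / (n_pclfs - cand)
               else numeric(0)
  )
  ok <- candidates$j[candidates$gradient < threshold]
  if (length(ok)) {
    list(n_proposed = min(ok), fallback = FALSE, candidates = candidates)
  } else {
    list(n_proposed = n_pclfs, fallback = TRUE, candidates = candidates)
  }
}

#' Final feature subset from importance scores
#'
#' Having fixed the subset size `n_proposed`, the relevant features are the
#' `n_proposed` highest-importance features among the `n_pclfs` active
#' (PCLFS-selected) features — the classifier's view of relevance overrides
#' simple ranking-prefix truncation. Ties are broken by PCLFS rank. Set
#' `rule = "prefix"` to instead truncate the PCLFS order.
#'
#' @param importance Numeric importance scores aligned to the first
#'   `n_pclfs` features of the ranking order (from
#'   [classifier_importance()] on the refitted model).
#' @param ranking The [pclfs_rank()] result.
#' @param n_proposed Target subset size (`<= length(importance)`).
#' @param rule `"importance"` (default) or `"prefix"`.
#' @return Integer vector of original feature indices, length `n_proposed`.
#' @export
ext_subset <- function(importance, ranking, n_proposed,
                       rule = c("importance", "prefix")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ranking, "pclfs_ranking"))
  n_active <- length(importance)
  if (n_proposed > n_active) {
    stop("n_proposed (", n_proposed, ") exceeds active feature count (",
         n_active, ")")
  }
  active <- ranking$order[seq_len(n_active)]
  if (rule == "prefix") return(active[seq_len(n_proposed)])
  pick <- order(-as.numeric(importance), seq_len(n_active))[seq_len(n_proposed)]
  active[pick]
}
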