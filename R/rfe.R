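#' Recursive feature elimination baseline
#'
#' Standard RFE with cross-validated subset-size choice: starting from all
#' features, the `step` least-important features (importance from a fit on
#' the full training data) are dropped repeatedly until one feature remains.
#' Each visited subset size is scored by stratified k-fold cross-validated
#' minority-class F1, and the size with the best mean CV score is returned
#' (ties go to the smaller subset).
#'
#' @param x Numeric feature matrix (training rows), or an [fs_data] object.
#' @param y Binary labels (ignored when `x` is an [fs_data]).
#' @param classifier Classifier id, see [classifiers].
#' @param step Number of features removed per iteration (default 1). A final
#'   partial step stops at one feature.
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param seed Optional seed controlling fold assignment and stochastic fits.
#' @return Object of class `"rfe_selection"`: list with `selected` (integer
#'   indices of the chosen subset), `scores` (data frame of `size` and
#'   `cv_f1` for every stage, largest size first), and `classifier`.
#' @export
#' @examples
#' d <- simulate_binary_data(200, 6, 2, class_sep = 2, seed = 3)
#' r <- rfe_select(d, cv_folds = 3, seed = 3)
#' r$selected
rfe_select <- function(x, y = NULL, classifier = "logit", step = 1,
                       cv_folds = 5, seed = NULL) {
  if (inherits(x, "fs_data")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- validate_labels(y)
  stopifnot(step >= 1, cv_folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  folds <- stratified_folds(y, cv_folds)

  active <- seq_len(ncol(x))
  stages <- list()
  repeat {
    cv <- cv_f1(x[, active, drop = FALSE], y, folds, classifier, seed)
    stages[[length(stages) + 1L]] <- list(active = active, cv_f1 = cv)
    if (length(active) == 1L) break
    fit <- fit_classifier(x[, active, drop = FALSE], y, classifier, seed = seed)
    imp <- classifier_importance(fit)
    drop_n <- min(step, length(active) - 1L)
    weakest <- order(imp, seq_along(imp))[seq_len(drop_n)]
    active <- active[-weakest]
  }

  sizes <- vapply(stages, function(s) length(s$active), integer(1))
  scores <- vapply(stages, function(s) s$cv_f1, numeric(1))
  # best mean CV F1; ties resolved in favour of fewer features
  best <- order(-scores, sizes)[1]
  structure(list(selected = sort(stages[[best]]$active),
                 scores = data.frame(size = sizes, cv_f1 = scores),
                 classifier = classifier),
            class = "rfe_selection")
}

#' @export
print.rfe_selection <- function(x, ...) {
  cat("<rfe_selection> ", length(x$selected), " features by ",
      x$classifier, " (best CV F1 = ",
      format(max(x$scores$cv_f1), digits = 4), ")\n", sep = "")
  invisible(x)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

cv_f1 <- function(x, y, folds, classifier, seed) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || !any(y[!tr] == 1L)) return(NA_real_)
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], classifier,
                          seed = if (is.null(seed)) NULL else seed + f)
    f1_score(y[!tr], predict_classifier(fit, x[!tr, , drop = FALSE]))
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}
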