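#' Fit PCLFS and its gradient-threshold extension
#'
#' `pclfs()` runs the complete wrapper feature-selection pipeline on a binary
#' classification dataset:
#'
#' 1. optional stratified train/test split (75/25 by default) and optional
#'    [smote()] rebalancing of the training rows;
#' 2. feature ranking by the sum of absolute first-two principal-component
#'    loadings ([pclfs_rank()]), computed on the (possibly rebalanced)
#'    training matrix only;
#' 3. the sequential F1 grid over nested subsets ([grid_scores()]);
#' 4. the PCLFS choice `n_pclfs` = smallest grid argmax ([pclfs_select()])
#'    and a refit at that size to obtain feature importances;
#' 5. the extension: per-feature threshold `t = tolerance / n`
#'    ([gradient_threshold()]), local-maximum candidates and the gradient
#'    rule ([ext_select()]), and the final importance-based subset
#'    ([ext_subset()]).
#'
#' If no candidate's gradient beats the threshold the extension falls back
#' to the PCLFS result. The realised F1 loss never exceeds `tolerance`.
#'
#' @param x A numeric feature matrix, an [fs_data] object, or a formula.
#' @param y Binary 0/1 labels (matrix interface only).
#' @param data A data frame (formula interface).
#' @param classifier Classifier id, see [classifiers]. Default `"logit"`.
#' @param tolerance Maximum tolerable total F1-score reduction (the
#'   user-defined budget spread over all features). Default 0.05.
#' @param test Optional held-out [fs_data] (or `list(x, y)`) to score on;
#'   when `NULL`, `test_fraction` of rows is split off internally.
#' @param test_fraction Proportion held out when `test` is `NULL`.
#'   Default 0.25.
#' @param smote Rebalance the training rows with [smote()]? Default `FALSE`.
#'   Never applied to test rows.
#' @param k_neighbors SMOTE neighbour count (default 5).
#' @param standardize Z-score columns before the PCA ranking. Default `TRUE`.
#' @param subset_rule `"importance"` (default) or `"prefix"`, see
#'   [ext_subset()].
#' @param seed Optional integer seed controlling the split, SMOTE and any
#'   stochastic classifier.
#' @param ... Passed between methods.
#'
#' @return An object of class `"pclfs"`; see Details. Key elements:
#'   `ranking`, `g` (the F1 grid), `n_pclfs`, `importance`, `threshold`,
#'   `candidates`, `n_proposed`, `fallback`, `subset` (original feature
#'   indices), `subset_names`, `f1_pclfs`, `f1_proposed`, `error_pclfs`,
#'   `error_proposed`, and `model` (the final classifier fitted on the
#'   proposed subset).
#' @seealso [summary.pclfs()], [plot.pclfs()], [predict.pclfs()],
#'   [rfe_select()] for the baseline.
#' @export
#' @examples
#' d <- simulate_binary_data(300, 12, 4, class_sep = 2, seed = 7)
#' fit <- pclfs(d, tolerance = 0.05, seed = 7)
#' fit
#' summary(fit)
pclfs <- function(x, ...) UseMethod("pclfs")

#' @rdname pclfs
#' @param formula A formula `label ~ .` (or with explicit feature terms);
#'   the response must be binary.
#' @export
pclfs.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- pclfs.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname pclfs
#' @export
pclfs.fs_data <- function(x, ...) {
  out <- pclfs.default(x$x, x$y, ...)
  out$informative <- x$informative
  out$call <- match.call()
  out
}

#' @rdname pclfs
#' @export
pclfs.default <- function(x, y, classifier = "logit", tolerance = 0.05,
                          test = NULL, test_fraction = 0.25, smote = FALSE,
                          k_neighbors = 5, standardize = TRUE,
                          subset_rule = c("importance", "prefix"),
                          seed = NULL, ...) {
  subset_rule <- match.arg(subset_rule)
  d <- fs_data(x, y)
  n <- ncol(d$x)

  if (is.null(test)) {
    sp <- split_dataset(d, test_fraction = test_fraction, stratify = TRUE,
                        seed = seed)
    train <- sp$train
    test <- sp$test
  } else {
    train <- d
    if (!inherits(test, "fs_data")) test <- fs_data(test$x, test$y)
    if (ncol(test$x) != n) stop("test set feature count differs from training")
  }

  if (isTRUE(smote)) {
    train <- smote.fs_data(train, k_neighbors = k_neighbors,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  }

  ranking <- pclfs_rank(train$x, standardize = standardize)
  grid <- grid_scores(train, test, ranking, classifier = classifier,
                      seed = if (is.null(seed)) NULL else seed + 1000L)
  g <- grid$g
  n_pclfs <- pclfs_select(g)

  # refit at the PCLFS size for importance scores
  active <- ranking$order[seq_len(n_pclfs)]
  refit <- fit_classifier(train$x[, active, drop = FALSE], train$y, classifier,
                          seed = if (is.null(seed)) NULL else seed + 2L)
  importance <- classifier_importance(refit)
  pred_pclfs <- predict_classifier(refit, test$x[, active, drop = FALSE])

  t <- gradient_threshold(tolerance, n)
  ext <- ext_select(g, n_pclfs, t)
  subset <- ext_subset(importance, ranking, ext$n_proposed, rule = subset_rule)

  final <- fit_classifier(train$x[, subset, drop = FALSE], train$y, classifier,
                          seed = if (is.null(seed)) NULL else seed + 3L)
  pred_final <- predict_classifier(final, test$x[, subset, drop = FALSE])

  structure(list(
    call = match.call(),
    classifier = classifier,
    tolerance = tolerance,
    threshold = t,
    n_features = n,
    feature_names = colnames(d$x),
    ranking = ranking,
    g = g,
    n_pclfs = n_pclfs,
    importance = importance,
    candidates = ext$candidates,
    n_proposed = ext$n_proposed,
    fallback = ext$fallback,
    subset = subset,
    subset_names = colnames(d$x)[subset],
    f1_pclfs = g[n_pclfs],
    f1_proposed = f1_score(test$y, pred_final),
    f1_grid_at_proposed = g[ext$n_proposed],
    error_pclfs = error_rate(test$y, pred_pclfs),
    error_proposed = error_rate(test$y, pred_final),
    model = final,
    smote = isTRUE(smote),
    seed = seed,
    train = train,
    test = test
  ), class = "pclfs")
}

#' @export
print.pclfs <- function(x, digits = 4, ...) {
  cat("PCLFS feature selection (", x$classifier, ")\n", sep = "")
  cat("  features: ", x$n_features,
      " | n_pclfs: ", x$n_pclfs,
      " | n_proposed: ", x$n_proposed,
      if (x$fallback) " (fallback to PCLFS)" else "", "\n", sep = "")
  cat("  F1 at PCLFS optimum: ", format(x$f1_pclfs, digits = digits),
      " | F1 on proposed subset: ", format(x$f1_proposed, digits = digits),
      "\n", sep = "")
  cat("  threshold t = tolerance/n = ",
      format(x$threshold, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Summarise a PCLFS fit
#'
#' @param object A [pclfs()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.pclfs"` with the grid, the candidate
#'   table and the selected subset.
#' @export
summary.pclfs <- function(object, ...) {
  structure(list(fit = object), class = "summary.pclfs")
}

#' @export
print.summary.pclfs <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nSelected subset (", length(f$subset), " features):\n  ",
      paste(f$subset_names, collapse = ", "), "\n", sep = "")
  if (nrow(f$candidates)) {
    cat("\nLocal-maximum candidates below the optimum:\n")
    print(cbind(round(f$candidates, digits),
                qualifies = f$candidates$gradient < f$threshold),
          row.names = FALSE)
  } else {
    cat("\nNo local-maximum candidates below the optimum.\n")
  }
  cat("\nRealised F1 loss vs optimum: ",
      format(f$f1_pclfs - f$f1_grid_at_proposed, digits = digits),
      " (budget ", format(f$tolerance, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' Plot the sequential F1 grid of a PCLFS fit
#'
#' Draws the grid curve with the PCLFS optimum (blue) and the proposed
#' reduced subset size (red); open circles mark local-maximum candidates.
#'
#' @param x A [pclfs()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pclfs <- function(x, ...) {
  graphics::plot(seq_along(x$g), x$g, type = "b", pch = 16, cex = 0.6,
                 xlab = "Number of selected features", ylab = "F1-score",
                 main = "Sequential feature-selection grid", ...)
  if (nrow(x$candidates)) {
    graphics::points(x$candidates$j, x$candidates$g, pch = 1, cex = 1.6)
  }
  graphics::points(x$n_pclfs, x$g[x$n_pclfs], pch = 19, col = "blue", cex = 1.3)
  graphics::points(x$n_proposed, x$g[x$n_proposed], pch = 19, col = "red",
                   cex = 1.3)
  graphics::legend("bottomright", legend = c("PCLFS", "proposed"),
                   col = c("blue", "red"), pch = 19, bty = "n")
  invisible(x)
}

#' Predict from the final reduced-subset model
#'
#' @param object A [pclfs()] fit.
#' @param newdata Feature matrix or data frame with the full original
#'   feature columns (the subset is extracted by name/position).
#' @param ... Unused.
#' @return Integer 0/1 predicted labels.
#' @export
predict.pclfs <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == object$n_features) {
    newdata <- newdata[, object$subset, drop = FALSE]
  } else if (ncol(newdata) != length(object$subset)) {
    stop("newdata must have all ", object$n_features,
         " original features or exactly the ", length(object$subset),
         " selected ones")
  }
  predict_classifier(object$model, newdata)
}

#' @export
coef.pclfs <- function(object, ...) {
  object$importance
}
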