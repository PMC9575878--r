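#' Supported classifier identifiers
#'
#' The feature-selection routines are classifier-agnostic: any model with a
#' notion of per-feature importance can drive the grid search and the final
#' subset choice. The built-in set mirrors common practice for tabular
#' binary classification:
#'
#' * `"logit"` — logistic regression ([stats::glm]); importance = |coefficient|.
#' * `"svm_linear"` — linear support vector machine ([e1071::svm]);
#'   importance = |w|, the primal weight vector recovered from the support
#'   vectors.
#' * `"decision_tree"` — CART ([rpart::rpart]); impurity-based importance,
#'   0 for unused features.
#' * `"random_forest"` — [randomForest::randomForest]; mean decrease in Gini.
#' * `"gbm"` — gradient-boosted trees (xgboost, if installed); gain-based
#'   importance. When xgboost is unavailable the id is rejected with an
#'   informative error, and [simulation harnesses][run_scenario] drop it
#'   with a warning instead of failing.
#'
#' @format NULL
#' @name classifiers
#' @aliases fit_classifier predict_classifier classifier_importance
NULL

CLASSIFIER_IDS <- c("logit", "svm_linear", "decision_tree", "random_forest", "gbm")

#' Fit a classifier on an active feature set
#'
#' Thin uniform wrapper over the supported model families (see
#' [classifiers]). Used internally by [grid_scores()], [rfe_select()] and
#' [pclfs()]; exported because custom workflows need the same interface.
#'
#' @param x Numeric feature matrix (training rows only).
#' @param y Binary 0/1 labels.
#' @param classifier One of `"logit"`, `"svm_linear"`, `"decision_tree"`,
#'   `"random_forest"`, `"gbm"`.
#' @param seed Optional seed applied before fitting (matters for the
#'   stochastic tree ensembles).
#' @return An object of class `"pclfsx_clf"` wrapping the underlying fit.
#' @export
fit_classifier <- function(x, y, classifier = "logit", seed = NULL) {
  classifier <- match.arg(classifier, CLASSIFIER_IDS)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  feat <- colnames(x)
  # model-safe column names, restored on output
  safe <- paste0("V", seq_len(ncol(x)))
  colnames(x) <- safe
  y <- validate_labels(y)
  if (!is.null(seed)) set.seed(seed)

  fit <- switch(classifier,
    logit = {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    },
    svm_linear = suppressWarnings(
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 scale = apply(x, 2, stats::sd) > 0)
    ),
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      # no surrogate splits: importance then reflects actual splits only,
      # so features the tree never uses score 0
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxsurrogate = 0))
    },
    random_forest = randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                               ntree = 300),
    gbm = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("classifier 'gbm' needs the xgboost package, which is not installed")
      }
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 50, verbose = 0)
    }
  )
  structure(list(classifier = classifier, fit = fit, features = feat,
                 safe_names = safe),
            class = "pclfsx_clf")
}

#' @rdname fit_classifier
#' @param object A fitted `"pclfsx_clf"`.
#' @param newx Feature matrix with the same columns the model was trained on.
#' @return For `predict_classifier()`, an integer 0/1 label vector.
#' @export
predict_classifier <- function(object, newx) {
  stopifnot(inherits(object, "pclfsx_clf"))
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$safe_names)) {
    stop("newx has ", ncol(newx), " columns; model expects ",
         length(object$safe_names))
  }
  colnames(newx) <- object$safe_names
  pred <- switch(object$classifier,
    logit = as.integer(
      stats::predict(object$fit, as.data.frame(newx), type = "response") > 0.5),
    svm_linear = as.integer(as.character(stats::predict(object$fit, newx))),
    decision_tree = as.integer(as.character(
      stats::predict(object$fit, as.data.frame(newx), type = "class"))),
    random_forest = as.integer(as.character(stats::predict(object$fit, newx))),
    gbm = as.integer(
      stats::predict(object$fit,
                     xgboost::xgb.DMatrix(newx, nthread = 1)) > 0.5)
  )
  pred
}

#' @rdname fit_classifier
#' @return For `classifier_importance()`, a non-negative numeric vector, one
#'   score per active feature (named by feature), on the model's own scale:
#'   only the relative order is used downstream.
#' @export
classifier_importance <- function(object) {
  stopifnot(inherits(object, "pclfsx_clf"))
  p <- length(object$safe_names)
  imp <- switch(object$classifier,
    logit = {
      cf <- stats::coef(object$fit)[-1]       # drop intercept
      cf[is.na(cf)] <- 0                      # aliased columns carry no signal
      abs(cf)[match(object$safe_names, names(cf))]
    },
    svm_linear = {
      w <- crossprod(object$fit$coefs, object$fit$SV)  # primal weights
      abs(as.numeric(w))[match(object$safe_names, colnames(object$fit$SV))]
    },
    decision_tree = {
      v <- object$fit$variable.importance
      out <- stats::setNames(numeric(p), object$safe_names)
      if (!is.null(v)) out[names(v)] <- v
      out
    },
    random_forest =
      randomForest::importance(object$fit)[object$safe_names, "MeanDecreaseGini"],
    gbm = {
      tab <- xgboost::xgb.importance(model = object$fit)
      out <- stats::setNames(numeric(p), object$safe_names)
      out[tab$Feature] <- tab$Gain
      out
    }
  )
  imp <- as.numeric(imp)
  imp[is.na(imp)] <- 0
  stats::setNames(imp, object$features)
}

#' @export
print.pclfsx_clf <- function(x, ...) {
  cat("<pclfsx_clf> ", x$classifier, " on ", length(x$features),
      " feature(s)\n", sep = "")
  invisible(x)
}
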