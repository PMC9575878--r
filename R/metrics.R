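#' Classification and feature-recovery metrics
#'
#' `f1_score()` is the harmonic mean of precision and recall for the positive
#' (minority, label 1) class, with the usual convention that it is 0 when
#' there are no true positives. `error_rate()` is the percent of
#' misclassified samples, `100 * (1 - accuracy)`.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @return A scalar: `f1_score()` in \[0, 1\], `error_rate()` in \[0, 100\].
#' @export
#' @examples
#' f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0))
f1_score <- function(y_true, y_pred) {
  y_true <- validate_labels(y_true)
  y_pred <- validate_labels(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == 1L & y_pred == 1L)
  if (tp == 0L) return(0)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' @rdname f1_score
#' @export
error_rate <- function(y_true, y_pred) {
  y_true <- validate_labels(y_true)
  y_pred <- validate_labels(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  100 * mean(y_true != y_pred)
}

#' Feature-selection recovery metrics
#'
#' In simulations the informative features are known, so a selection can be
#' scored as a per-feature binary decision. `tpr_fs()` is the
#' feature-selection true positive rate, the fraction of truly informative
#' features recovered. `correct_pct()` is the per-feature classification
#' accuracy of the selection as a percent:
#' `100 * (TP + TN) / n`, where TP counts informative features selected and
#' TN noise features left out. Both are invariant to relabelling features.
#'
#' @param selected Integer indices of the selected features.
#' @param informative Integer indices of the truly informative features
#'   (non-empty for `tpr_fs()`).
#' @param n Total number of features.
#' @return `tpr_fs()` in \[0, 1\]; `correct_pct()` in \[0, 100\].
#' @export
#' @examples
#' tpr_fs(c(1, 2, 3), c(2, 3, 4, 5))
#' correct_pct(c(1, 2, 3, 8), 1:5, 10)
tpr_fs <- function(selected, informative) {
  if (length(informative) == 0L) {
    stop("tpr_fs is undefined with no informative features")
  }
  length(intersect(selected, informative)) / length(informative)
}

#' @rdname tpr_fs
#' @export
correct_pct <- function(selected, informative, n) {
  stopifnot(n >= 1)
  tp <- length(intersect(selected, informative))
  tn <- length(setdiff(setdiff(seq_len(n), selected), informative))
  100 * (tp + tn) / n
}

#' Feature-reduction and F1-change bookkeeping against a baseline
#'
#' Summarises a method-comparison table row: how many features the final
#' method saved relative to a baseline selection (as a percent of the
#' dataset's total feature count) and the change in F1-score. Negative
#' reduction means the final method kept more features than the baseline;
#' negative F1 change means it scored lower.
#'
#' \deqn{reduction\% = 100 (n_{baseline} - n_{final}) / n_{total}}
#'
#' @param n_total Total number of features in the dataset.
#' @param n_baseline,f1_baseline Subset size and F1-score of the baseline
#'   method (e.g. RFE).
#' @param n_final,f1_final Subset size and F1-score of the method being
#'   reported (e.g. PCLFS-ext, or PCLFS where the extension falls back).
#' @return A list with `feature_reduction_pct` and `f1_change`.
#' @export
#' @examples
#' selection_report(44, n_baseline = 36, f1_baseline = 0.6957,
#'                  n_final = 11, f1_final = 0.6939)
selection_report <- function(n_total, n_baseline, f1_baseline,
                             n_final, f1_final) {
  stopifnot(n_total >= 1)
  list(feature_reduction_pct = 100 * (n_baseline - n_final) / n_total,
       f1_change = f1_final - f1_baseline)
}
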