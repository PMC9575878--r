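#' First-two principal-component loadings
#'
#' Returns the loadings (unit-norm eigenvector coefficients) of the first two
#' principal components of a feature matrix. Columns are z-scored first by
#' default, i.e. the PCA is on the correlation matrix: loadings are
#' scale-dependent, and real datasets mix measurement scales, so the
#' correlation form is the defensible default (it can be switched off for
#' data already on a common scale). A column that is constant after centering
#' is divided by 1 instead of 0, with a warning.
#'
#' Eigenvector signs are arbitrary; downstream ranking uses absolute values,
#' so the sign never matters.
#'
#' @param x Numeric matrix, at least 2 rows.
#' @param standardize Z-score columns before the decomposition? Default `TRUE`.
#' @return A list with numeric vectors `pc1` and `pc2` (length `ncol(x)`).
#'   With a single feature, or a rank-1 matrix, `pc2` is all zeros.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' pc_loadings(x)
pc_loadings <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows for PCA")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    if (any(s == 0)) {
      warning("constant column(s) ", paste(which(s == 0), collapse = ", "),
              " left unscaled")
      s[s == 0] <- 1
    }
    x <- sweep(x, 2, s, "/")
  }
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  n <- ncol(x)
  pc1 <- p$rotation[, 1]
  pc2 <- if (ncol(p$rotation) >= 2) p$rotation[, 2] else numeric(n)
  list(pc1 = as.numeric(pc1), pc2 = as.numeric(pc2))
}

#' Rank features by principal-component loadings
#'
#' The PCLFS ranking criterion: each feature's score is the sum of the
#' absolute values of its loadings on the first two principal components,
#' and features are ordered by decreasing score. Ties are broken by
#' ascending original column index. The ranking is independent of the
#' classifier used later, and (with standardization) invariant to rescaling
#' any feature.
#'
#' @inheritParams pc_loadings
#' @return An object of class `"pclfs_ranking"`: list with `order` (integer
#'   permutation of `1:n`, most informative first), `scores` (per-feature
#'   score, in original column order) and `feature_names`.
#' @seealso [grid_scores()], [pclfs()]
#' @export
#' @examples
#' d <- simulate_binary_data(300, 8, 3, class_sep = 2, seed = 1)
#' r <- pclfs_rank(d$x)
#' r$order
pclfs_rank <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  l <- pc_loadings(x, standardize = standardize)
  scores <- abs(l$pc1) + abs(l$pc2)
  # round away eigensolver noise so exact ties break by column index
  ord <- order(-signif(scores, 8), seq_along(scores))
  structure(list(order = ord, scores = scores,
                 feature_names = colnames(x)),
            class = "pclfs_ranking")
}

#' @export
print.pclfs_ranking <- function(x, ...) {
  n <- length(x$order)
  cat("<pclfs_ranking> ", n, " features\n", sep = "")
  top <- utils::head(x$order, 10L)
  lab <- if (is.null(x$feature_names)) top else x$feature_names[top]
  cat("top:", paste(lab, collapse = " "),
      if (n > 10L) "..." else "", "\n")
  invisible(x)
}
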