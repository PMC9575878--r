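#' Feature-selection dataset container
#'
#' Bundles a numeric feature matrix with a binary class label and, for
#' simulated data, the ground-truth informative-feature mask. The minority
#' (positive, "abnormal") class is always coded `1` and the majority class
#' `0`; every classification metric in the package treats class 1 as the
#' F1-positive class.
#'
#' @param x Numeric matrix or data frame, one row per sample, one column per
#'   feature. No missing values.
#' @param y Binary label vector (`0`/`1`, logical, or a two-level factor whose
#'   first level maps to 0). Length must equal `nrow(x)`.
#' @param feature_names Optional character vector of column names; defaults to
#'   existing column names or `f1..fn`.
#' @param informative Optional logical vector marking which columns carry
#'   class signal (ground truth in simulations).
#'
#' @return An object of class `"fs_data"`: a list with elements `x` (numeric
#'   matrix with column names), `y` (integer 0/1), and `informative` (logical
#'   or `NULL`).
#' @seealso [simulate_binary_data()], [split_dataset()], [smote()]
#' @export
#' @examples
#' d <- fs_data(matrix(rnorm(40), 10, 4), rep(c(0, 1), 5))
#' d
fs_data <- function(x, y, feature_names = NULL, informative = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (anyNA(x)) stop("feature matrix contains missing values")
  y <- validate_labels(y)
  if (length(y) != nrow(x)) {
    stop("label length (", length(y), ") does not match rows (", nrow(x), ")")
  }
  if (is.null(feature_names)) feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(x)))
  if (length(feature_names) != ncol(x)) stop("feature_names length mismatch")
  colnames(x) <- feature_names
  if (!is.null(informative)) {
    informative <- as.logical(informative)
    if (length(informative) != ncol(x)) stop("informative mask length mismatch")
  }
  structure(list(x = x, y = y, informative = informative), class = "fs_data")
}

# Coerce labels to integer 0/1; two-level factors map first level -> 0.
validate_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("class label must have exactly two levels")
    y <- as.integer(y) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  } else {
    y <- as.integer(y)
    if (anyNA(y)) stop("class label contains missing values")
  }
  if (!all(y %in% c(0L, 1L))) stop("class label must be binary (0/1)")
  y
}

#' @export
print.fs_data <- function(x, ...) {
  cat("<fs_data> ", nrow(x$x), " samples x ", ncol(x$x), " features; class 1: ",
      sum(x$y == 1L), "/", length(x$y), sep = "")
  if (!is.null(x$informative)) {
    cat("; informative features: ", sum(x$informative), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.fs_data <- function(x) dim(x$x)

#' @export
as.data.frame.fs_data <- function(x, row.names = NULL, optional = FALSE,
                                  label = "class", ...) {
  df <- as.data.frame(x$x, row.names = row.names, optional = optional, ...)
  df[[label]] <- x$y
  df
}
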