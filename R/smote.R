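#' SMOTE: synthetic minority oversampling
#'
#' Balances a binary dataset by interpolating synthetic minority samples.
#' Each synthetic row is `x + u * (x_nn - x)` for a randomly chosen minority
#' row `x`, one of its `k_neighbors` nearest minority neighbours `x_nn`
#' (Euclidean distance), and `u ~ Uniform(0, 1)`. Original rows are kept
#' unchanged; only the minority class is oversampled, up to exact balance.
#'
#' Apply SMOTE to the training partition only — resampling test rows would
#' leak synthetic copies of them into evaluation.
#'
#' @param data An [fs_data] object, or a numeric feature matrix when `y` is
#'   supplied.
#' @param y Binary labels (only for the matrix interface).
#' @param k_neighbors Number of nearest minority neighbours to interpolate
#'   towards (default 5). If the minority class has fewer than
#'   `k_neighbors + 1` members, `k_neighbors` is reduced with a warning.
#' @param seed Optional integer seed.
#' @param ... Passed between methods.
#'
#' @return An object of the same kind as the input (`fs_data`, or a list with
#'   `x` and `y`) with classes exactly balanced and an additional logical
#'   vector `synthetic` marking generated rows.
#' @export
#' @examples
#' d <- simulate_binary_data(100, 4, 2, class_weights = c(0.8, 0.2), seed = 1)
#' b <- smote(d, seed = 1)
#' table(b$y)
smote <- function(data, ...) UseMethod("smote")

#' @rdname smote
#' @export
smote.fs_data <- function(data, k_neighbors = 5, seed = NULL, ...) {
  res <- smote_xy(data$x, data$y, k_neighbors, seed)
  out <- fs_data(res$x, res$y, informative = data$informative)
  out$synthetic <- res$synthetic
  out
}

#' @rdname smote
#' @export
smote.default <- function(data, y, k_neighbors = 5, seed = NULL, ...) {
  smote_xy(as.matrix(data), validate_labels(y), k_neighbors, seed)
}

smote_xy <- function(x, y, k_neighbors, seed) {
  stopifnot(k_neighbors >= 1)
  counts <- tabulate(y + 1L, 2L)
  if (any(counts == 0L)) stop("SMOTE requires both classes present")
  n_new <- counts[1] - counts[2]
  if (n_new < 0) stop("class 1 must be the minority (or classes balanced)")
  if (n_new == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  minority <- which(y == 1L)
  if (length(minority) < 2L) {
    stop("SMOTE needs at least two minority samples to interpolate")
  }
  if (k_neighbors > length(minority) - 1L) {
    k_neighbors <- length(minority) - 1L
    warning("k_neighbors reduced to ", k_neighbors,
            " (minority class has only ", length(minority), " samples)")
  }
  if (!is.null(seed)) set.seed(seed)

  xm <- x[minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  # k nearest minority neighbours of each minority row
  nn <- apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)])
  nn <- matrix(nn, nrow = k_neighbors)

  base <- sample.int(length(minority), n_new, replace = TRUE)
  pick <- sample.int(k_neighbors, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] +
    u * (xm[nn[cbind(pick, base)], , drop = FALSE] - xm[base, , drop = FALSE])

  list(x = rbind(x, synth),
       y = c(y, rep(1L, n_new)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
}
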