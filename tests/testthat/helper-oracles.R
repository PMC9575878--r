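# Independent brute-force reference for the gradient-threshold selection:
# scans every index below the grid optimum, applies the local-maximum and
# gradient conditions directly, returns the first (smallest) qualifying index.
brute_force_ext <- function(g, t) {
  n_pclfs <- which(g == max(g))[1]
  for (j in seq_len(max(n_pclfs - 1L, 0L))) {
    left <- if (j == 1L) -Inf else g[j - 1L]
    is_peak <- g[j] > left && g[j] > g[j + 1L]
    if (is_peak && (g[n_pclfs] - g[j]) / (n_pclfs - j) < t) {
      return(list(n_proposed = j, fallback = FALSE))
    }
  }
  list(n_proposed = n_pclfs, fallback = TRUE)
}

# Random F1-like grid: noisy saturating curve, values clamped to [0, 1].
random_grid <- function(n) {
  base <- 1 - exp(-seq_len(n) / stats::runif(1, 1, n))
  g <- base * stats::runif(1, 0.4, 1) + stats::rnorm(n, 0, 0.05)
  pmin(pmax(g, 0), 1)
}

# Confusion-matrix F1, computed from first principles (test oracle).
f1_from_confusion <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Point-biserial correlation of each feature column with the binary label.
point_biserial <- function(x, y) {
  apply(x, 2, function(col) stats::cor(col, y))
}
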