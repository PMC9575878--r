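#' Packaged demonstration grid
#'
#' A synthetic 30-feature sequential F1 grid shipped with the package
#' (`extdata/demo_grid_synthetic.csv`), shaped like the classic worked
#' example of the method: the curve climbs steeply while the 10 informative
#' features are being added, peaks locally at size 10, then drifts up by
#' sampling noise to a slightly higher global maximum at size 29. The
#' original maximum-F1 rule therefore keeps 29 features, while the
#' gradient-threshold extension (tolerance 0.05, threshold 0.05/30) keeps
#' 10 — the informative count. The grid is constructed, not simulated; it
#' exists so the selection arithmetic can be demonstrated and tested on a
#' fixed input.
#'
#' @return A list with `g` (numeric length 30 grid), `n_informative` (10)
#'   and `tolerance` (0.05).
#' @export
#' @examples
#' demo <- demo_grid()
#' n_max <- pclfs_select(demo$g)
#' ext_select(demo$g, n_max, gradient_threshold(demo$tolerance, length(demo$g)))
demo_grid <- function() {
  path <- system.file("extdata", "demo_grid_synthetic.csv",
                      package = "pclfsx", mustWork = TRUE)
  df <- utils::read.csv(path)
  list(g = df$f1, n_informative = 10L, tolerance = 0.05)
}
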