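#' One simulation replicate comparing RFE, PCLFS and PCLFS-ext
#'
#' Generates a synthetic dataset with known informative features, splits it
#' 75/25 stratified, optionally rebalances the training rows with SMOTE, and
#' runs the requested methods on the shared data. Each method is scored by
#' held-out minority-class F1, error rate, subset size, feature-selection
#' TPR and per-feature correct percentage against the ground-truth mask.
#'
#' @param n_samples,n_features,n_informative,class_weights,class_sep
#'   Passed to [simulate_binary_data()].
#' @param classifier Classifier id, see [classifiers].
#' @param smote Rebalance the training rows? Default `FALSE`.
#' @param tolerance Extension budget (default 0.05); threshold is
#'   `tolerance / n_features`.
#' @param rep_seed Integer seed; fully determines the replicate.
#' @param methods Subset of `c("rfe", "pclfs", "pclfs_ext")` to run.
#' @param test_fraction Held-out proportion (default 0.25).
#' @param rfe_cv_folds CV folds for the RFE baseline (default 5).
#' @return A data frame with one row per method and columns `method`,
#'   `n_informative`, `f1`, `error_rate`, `n_selected`, `tpr_fs`,
#'   `correct_pct`, `seed`.
#' @export
run_replicate <- function(n_samples, n_features, n_informative,
                          class_weights = c(0.5, 0.5), class_sep = 1,
                          classifier = "logit", smote = FALSE,
                          tolerance = 0.05, rep_seed = 1,
                          methods = c("rfe", "pclfs", "pclfs_ext"),
                          test_fraction = 0.25, rfe_cv_folds = 5) {
  methods <- match.arg(methods, several.ok = TRUE)
  d <- simulate_binary_data(n_samples, n_features, n_informative,
                            class_weights, class_sep, seed = rep_seed)
  sp <- split_dataset(d, test_fraction, stratify = TRUE, seed = rep_seed + 1L)
  train <- sp$train
  test <- sp$test
  if (isTRUE(smote)) {
    train <- smote.fs_data(train, seed = rep_seed + 2L)
  }
  informative <- which(d$informative)

  rows <- list()
  measure <- function(method, selected, f1, err) {
    data.frame(method = method, n_informative = n_informative, f1 = f1,
               error_rate = err, n_selected = length(selected),
               tpr_fs = if (length(informative)) tpr_fs(selected, informative)
                        else NA_real_,
               correct_pct = correct_pct(selected, informative, n_features),
               seed = rep_seed)
  }

  if ("rfe" %in% methods) {
    r <- rfe_select(train$x, train$y, classifier, cv_folds = rfe_cv_folds,
                    seed = rep_seed + 3L)
    fit <- fit_classifier(train$x[, r$selected, drop = FALSE], train$y,
                          classifier, seed = rep_seed + 4L)
    pred <- predict_classifier(fit, test$x[, r$selected, drop = FALSE])
    rows$rfe <- measure("rfe", r$selected, f1_score(test$y, pred),
                        error_rate(test$y, pred))
  }

  if (any(c("pclfs", "pclfs_ext") %in% methods)) {
    fit <- pclfs.default(train$x, train$y, classifier = classifier,
                         tolerance = tolerance, test = test,
                         seed = rep_seed + 5L)
    if ("pclfs" %in% methods) {
      rows$pclfs <- measure("pclfs",
                            fit$ranking$order[seq_len(fit$n_pclfs)],
                            fit$f1_pclfs, fit$error_pclfs)
    }
    if ("pclfs_ext" %in% methods) {
      rows$pclfs_ext <- measure("pclfs_ext", fit$subset, fit$f1_proposed,
                                fit$error_proposed)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run a replicated simulation scenario
#'
#' Sweeps the number of informative features over `n_informative`, running
#' `replicates` independent datasets per sweep value (replicate `r` uses
#' seed `base_seed + r`, so partial reruns are reproducible), and aggregates
#' each metric per method and sweep value.
#'
#' A replicate whose generated split degenerates (a class missing from a
#' partition) is skipped with a warning and excluded from the denominators.
#' When `classifier = "gbm"` and xgboost is unavailable, the scenario
#' downgrades to `"logit"` with a warning rather than failing.
#'
#' @inheritParams run_replicate
#' @param n_informative Integer vector to sweep over.
#' @param replicates Number of replicates per sweep value (default 100).
#' @param base_seed Base seed (default 1).
#' @return Object of class `"pclfs_sim"`: list with `records` (one row per
#'   method x sweep x replicate) and `summary`, a tidy long data frame keyed
#'   by (`method`, `n_informative`, `metric`) with columns `mean`, `sd`,
#'   `best` (minimum for `error_rate`, maximum otherwise) and `n_reps`.
#' @export
#' @examples
#' sim <- run_scenario(n_samples = 150, n_features = 6, n_informative = c(2, 4),
#'                     class_sep = 2, replicates = 2, base_seed = 1,
#'                     methods = "pclfs_ext", rfe_cv_folds = 3)
#' head(sim$summary)
run_scenario <- function(n_samples = 1000, n_features = 30,
                         n_informative = seq_len(n_features),
                         class_weights = c(0.5, 0.5), class_sep = 1,
                         classifier = "logit", smote = FALSE,
                         tolerance = 0.05, replicates = 100, base_seed = 1,
                         methods = c("rfe", "pclfs", "pclfs_ext"),
                         test_fraction = 0.25, rfe_cv_folds = 5) {
  stopifnot(replicates >= 1, all(n_informative <= n_features))
  if (classifier == "gbm" && !requireNamespace("xgboost", quietly = TRUE)) {
    warning("xgboost not installed; falling back to classifier = 'logit'")
    classifier <- "logit"
  }
  records <- list()
  for (k in n_informative) {
    for (r in seq_len(replicates)) {
      rec <- tryCatch(
        run_replicate(n_samples, n_features, k, class_weights, class_sep,
                      classifier, smote, tolerance,
                      rep_seed = base_seed + r + 100000L * match(k, n_informative),
                      methods = methods, test_fraction = test_fraction,
                      rfe_cv_folds = rfe_cv_folds),
        error = function(e) {
          warning("replicate ", r, " (n_informative = ", k, ") skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  if (!length(records)) stop("every replicate failed")
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  structure(list(records = records,
                 summary = summarise_records(records),
                 scenario = list(n_samples = n_samples,
                                 n_features = n_features,
                                 class_weights = class_weights,
                                 class_sep = class_sep,
                                 classifier = classifier, smote = smote,
                                 tolerance = tolerance,
                                 replicates = replicates,
                                 base_seed = base_seed)),
            class = "pclfs_sim")
}

summarise_records <- function(records) {
  metrics <- c("f1", "error_rate", "n_selected", "tpr_fs", "correct_pct")
  out <- list()
  for (m in metrics) {
    agg <- stats::aggregate(records[[m]],
                            by = list(method = records$method,
                                      n_informative = records$n_informative),
                            FUN = function(v) c(
                              mean = mean(v),
                              sd = if (length(v) > 1) stats::sd(v) else 0,
                              best = if (m == "error_rate") min(v) else max(v),
                              n_reps = length(v)))
    out[[m]] <- data.frame(method = agg$method,
                           n_informative = agg$n_informative,
                           metric = m,
                           mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                           best = agg$x[, "best"], n_reps = agg$x[, "n_reps"])
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$method, res$n_informative, res$metric), , drop = FALSE]
}

#' @export
print.pclfs_sim <- function(x, ...) {
  s <- x$scenario
  cat("<pclfs_sim> ", nrow(x$records), " method-replicates | ",
      s$classifier, ", n = ", s$n_samples, ", p = ", s$n_features,
      ", imbalance ", paste(s$class_weights, collapse = ":"),
      if (s$smote) ", SMOTE" else "", "\n", sep = "")
  invisible(x)
}

#' Write and re-read simulation results
#'
#' `write_simulation()` writes the raw replicate records and the aggregated
#' summary as TSV, plus the summary (with the scenario settings) as JSON —
#' the long-format tables behind the method-comparison figures. The
#' `records.tsv`/`summary.tsv` round trip through `read_simulation()` is
#' exact up to numeric printing (15 significant digits).
#'
#' @param sim A [run_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `write_simulation()` returns the directory invisibly;
#'   `read_simulation()` returns a list with `records` and `summary` data
#'   frames.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pclfs_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    utils::write.table(format(df, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(sim$records, file.path(dir, "records.tsv"))
  write_tsv(sim$summary, file.path(dir, "summary.tsv"))
  jsonlite::write_json(list(scenario = sim$scenario, summary = sim$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_simulation
#' @export
read_simulation <- function(dir) {
  list(records = utils::read.delim(file.path(dir, "records.tsv")),
       summary = utils::read.delim(file.path(dir, "summary.tsv")))
}
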