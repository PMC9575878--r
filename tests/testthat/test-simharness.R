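test_that("a replicate is fully determined by its seed", {
  a <- run_replicate(120, 5, 2, class_sep = 2, rep_seed = 9, rfe_cv_folds = 3)
  b <- run_replicate(120, 5, 2, class_sep = 2, rep_seed = 9, rfe_cv_folds = 3)
  expect_identical(a, b)
  expect_setequal(a$method, c("rfe", "pclfs", "pclfs_ext"))
})

test_that("zero tolerance makes the extension record equal the PCLFS record", {
  r <- run_replicate(150, 6, 3, class_sep = 2, tolerance = 0, rep_seed = 4,
                     methods = c("pclfs", "pclfs_ext"))
  pc <- r[r$method == "pclfs", !(names(r) %in% "method")]
  ext <- r[r$method == "pclfs_ext", !(names(r) %in% "method")]
  expect_equal(ext$n_selected, pc$n_selected)
  expect_equal(ext$tpr_fs, pc$tpr_fs)
  expect_equal(ext$correct_pct, pc$correct_pct)
})

test_that("when all features are informative, tpr_fs is n_selected / n", {
  r <- run_replicate(150, 5, 5, class_sep = 2, rep_seed = 6, rfe_cv_folds = 3)
  expect_equal(r$tpr_fs, r$n_selected / 5)
})

test_that("scenario aggregation bookkeeping is exact", {
  sim <- run_scenario(n_samples = 120, n_features = 5, n_informative = c(2, 4),
                      class_sep = 2, replicates = 2, base_seed = 3,
                      rfe_cv_folds = 3)
  # rows = methods x sweep x metrics
  expect_equal(nrow(sim$summary), 3L * 2L * 5L)
  expect_true(all(sim$summary$n_reps == 2))
  expect_true(all(sim$summary$sd >= 0))
  one <- run_scenario(n_samples = 120, n_features = 5, n_informative = 2,
                      class_sep = 2, replicates = 1, base_seed = 3,
                      methods = "pclfs", rfe_cv_folds = 3)
  expect_true(all(one$summary$sd == 0))
})

test_that("written simulation tables round-trip through TSV", {
  sim <- run_scenario(n_samples = 100, n_features = 4, n_informative = 2,
                      class_sep = 2, replicates = 2, base_seed = 8,
                      methods = c("pclfs", "pclfs_ext"), rfe_cv_folds = 3)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("records.tsv", "summary.tsv",
                                               "summary.json")))))
  back <- read_simulation(dir)
  expect_equal(back$records$f1, sim$records$f1, tolerance = 1e-12)
  expect_equal(back$summary$mean, sim$summary$mean, tolerance = 1e-12)
  expect_equal(back$summary$method, as.character(sim$summary$method))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$scenario$n_features, 4L)
})

test_that("uninformative balanced data yields chance-level F1 for all methods", {
  sim <- run_scenario(n_samples = 1000, n_features = 8, n_informative = 0,
                      replicates = 20, base_seed = 17, rfe_cv_folds = 3)
  f1s <- sim$summary[sim$summary$metric == "f1", ]
  expect_true(all(abs(f1s$mean - 0.5) < 0.1))
})

test_that("the extension never selects more features than PCLFS on average", {
  sim <- run_scenario(n_samples = 300, n_features = 10,
                      n_informative = c(3, 6), class_sep = 1.5,
                      class_weights = c(0.7, 0.3), replicates = 4,
                      base_seed = 21, methods = c("pclfs", "pclfs_ext"))
  ns <- sim$summary[sim$summary$metric == "n_selected", ]
  for (k in c(3, 6)) {
    expect_lte(ns$mean[ns$method == "pclfs_ext" & ns$n_informative == k],
               ns$mean[ns$method == "pclfs" & ns$n_informative == k])
  }
})

test_that("feature recovery of the extension beats RFE on imbalanced data", {
  sim <- run_scenario(n_samples = 600, n_features = 15, n_informative = 5,
                      class_weights = c(0.9, 0.1), class_sep = 2,
                      replicates = 6, base_seed = 29, rfe_cv_folds = 3)
  tpr <- sim$summary[sim$summary$metric == "tpr_fs", ]
  expect_gte(tpr$mean[tpr$method == "pclfs_ext"],
             tpr$mean[tpr$method == "rfe"])
})
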