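test_that("the grid has one score per nested subset and is deterministic", {
  d <- simulate_binary_data(40, 4, 2, class_sep = 2, seed = 44)
  sp <- split_dataset(d, 0.25, seed = 44)
  g1 <- grid_scores(sp$train, sp$test, classifier = "logit", seed = 44)
  g2 <- grid_scores(sp$train, sp$test, classifier = "logit", seed = 44)
  expect_length(g1$g, 4L)
  expect_true(all(g1$g >= 0 & g1$g <= 1))
  expect_identical(g1$g, g2$g)
})

test_that("a perfectly separating first feature scores F1 = 1 immediately", {
  x <- cbind(sep = c(rnorm(40, -6), rnorm(40, 6)), n1 = rnorm(80),
             n2 = rnorm(80))
  y <- rep(c(0L, 1L), each = 40)
  d <- fs_data(x, y)
  sp <- split_dataset(d, 0.25, seed = 7)
  ranking <- structure(list(order = 1:3, scores = c(3, 2, 1),
                            feature_names = colnames(x)),
                       class = "pclfs_ranking")
  g <- grid_scores(sp$train, sp$test, ranking, classifier = "decision_tree",
                   seed = 7)
  expect_equal(g$g[1], 1)
})

test_that("pclfs_select is the smallest argmax", {
  expect_equal(pclfs_select(c(0.2, 0.9, 0.9)), 2L)
  expect_equal(pclfs_select(0.5), 1L)
  expect_equal(pclfs_select(seq(0.1, 0.9, length.out = 7)), 7L)
  expect_error(pclfs_select(numeric(0)), "empty")
})

test_that("local maxima follow the strict neighbour rule with edge handling", {
  g <- c(0.60, 0.70, 0.65, 0.72, 0.71, 0.80)
  expect_equal(local_maxima(g, 6L), c(2L, 4L))
  expect_equal(local_maxima(seq(0.1, 0.8, length.out = 6), 6L), integer(0))
  # left-edge peak qualifies (missing left neighbour treated as -Inf)
  expect_equal(local_maxima(c(0.9, 0.5, 0.4, 1.0), 4L), 1L)
  # plateau (tie with neighbour) does not qualify
  expect_equal(local_maxima(c(0.5, 0.7, 0.7, 0.9), 4L), integer(0))
})

test_that("threshold is tolerance spread over the total feature count", {
  expect_equal(round(gradient_threshold(0.05, 44), 4), 0.0011)
  expect_equal(round(gradient_threshold(0.05, 30), 4), 0.0017)
  expect_equal(gradient_threshold(0, 999), 0)
  expect_error(gradient_threshold(-0.01, 10), "non-negative")
})

test_that("ext_select applies the gradient rule, with fallback", {
  g <- c(0.60, 0.70, 0.65, 0.72, 0.71, 0.80)
  sel <- ext_select(g, 6L, 0.03)
  expect_equal(sel$candidates$j, c(2L, 4L))
  expect_equal(sel$candidates$gradient, c(0.025, 0.04))
  expect_equal(sel$n_proposed, 2L)
  expect_false(sel$fallback)

  tight <- ext_select(g, 6L, 1e-4)
  expect_equal(tight$n_proposed, 6L)
  expect_true(tight$fallback)

  single <- ext_select(0.7, 1L, 0.05)   # n_pclfs = 1: nothing below it
  expect_true(single$fallback)
  expect_equal(single$n_proposed, 1L)
})

test_that("ext_select matches the brute-force enumerator on random grids", {
  set.seed(77)
  for (i in 1:300) {
    g <- random_grid(sample(3:50, 1))
    t <- 10^runif(1, -4, -0.5)
    n_pclfs <- pclfs_select(g)
    got <- ext_select(g, n_pclfs, t)
    want <- brute_force_ext(g, t)
    expect_equal(got$n_proposed, want$n_proposed)
    expect_equal(got$fallback, want$fallback)
  }
})

test_that("candidate gradients are non-negative and the loss bound holds", {
  set.seed(88)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    g <- random_grid(n)
    tolerance <- runif(1, 0, 0.2)
    n_pclfs <- pclfs_select(g)
    sel <- ext_select(g, n_pclfs, gradient_threshold(tolerance, n))
    expect_true(all(sel$candidates$gradient >= 0))
    expect_lte(g[n_pclfs] - g[sel$n_proposed], tolerance + 1e-12)
  }
})

test_that("n_proposed is non-increasing in the tolerance on a fixed grid", {
  set.seed(99)
  for (i in 1:100) {
    g <- random_grid(sample(5:40, 1))
    n_pclfs <- pclfs_select(g)
    tols <- sort(runif(5, 0, 0.3))
    sizes <- vapply(tols, function(tol) {
      ext_select(g, n_pclfs, gradient_threshold(tol, length(g)))$n_proposed
    }, integer(1))
    expect_true(all(diff(sizes) <= 0L))
  }
})

test_that("ext_subset picks top-importance features among the active set", {
  r <- structure(list(order = c(3L, 1L, 4L, 2L), scores = c(4, 2, 6, 1)),
                 class = "pclfs_ranking")
  # active = first 3 of the order: features 3, 1, 4
  expect_setequal(ext_subset(c(0.1, 0.9, 0.5), r, 2L), c(1L, 4L))
  expect_setequal(ext_subset(c(0.1, 0.9, 0.5), r, 3L), c(3L, 1L, 4L))
  # equal importances: fall back to ranking order
  expect_equal(ext_subset(c(0.5, 0.5, 0.5), r, 2L), c(3L, 1L))
  # prefix rule truncates the ranking order regardless of importance
  expect_equal(ext_subset(c(0.1, 0.9, 0.5), r, 2L, rule = "prefix"),
               c(3L, 1L))
  expect_error(ext_subset(c(0.1, 0.9), r, 3L), "exceeds")
})

test_that("zero tolerance always falls back to the PCLFS selection", {
  d <- simulate_binary_data(200, 8, 3, class_sep = 1.5, seed = 15)
  fit <- pclfs(d, tolerance = 0, seed = 15)
  expect_true(fit$fallback)
  expect_equal(fit$n_proposed, fit$n_pclfs)
  expect_setequal(fit$subset, fit$ranking$order[seq_len(fit$n_pclfs)])
})

test_that("end-to-end fits respect the size and loss contracts", {
  for (s in c(1, 2, 3)) {
    d <- simulate_binary_data(250, 10, 4, class_sep = 1.5,
                              class_weights = c(0.7, 0.3), seed = 200 + s)
    fit <- pclfs(d, tolerance = 0.1, seed = 200 + s)
    expect_lte(fit$n_proposed, fit$n_pclfs)
    expect_equal(length(fit$subset), fit$n_proposed)
    expect_lte(fit$f1_pclfs - fit$f1_grid_at_proposed, 0.1 + 1e-12)
    expect_true(all(fit$subset %in% fit$ranking$order[seq_len(fit$n_pclfs)]))
  }
})

test_that("formula and matrix interfaces agree", {
  d <- simulate_binary_data(150, 5, 2, class_sep = 2, seed = 77)
  df <- as.data.frame(d)
  f1 <- pclfs(class ~ ., data = df, seed = 77)
  f2 <- pclfs(d$x, d$y, seed = 77)
  expect_equal(f1$g, f2$g)
  expect_equal(f1$subset, f2$subset)
})

test_that("predictions come from the reduced-subset model", {
  d <- simulate_binary_data(200, 6, 3, class_sep = 2, seed = 33)
  fit <- pclfs(d, seed = 33)
  p_full <- predict(fit, d$x)                 # full columns, subset extracted
  p_sub <- predict(fit, d$x[, fit$subset, drop = FALSE])
  expect_identical(p_full, p_sub)
  expect_gt(f1_score(d$y, p_full), 0.8)
  expect_error(predict(fit, cbind(d$x, extra = 0)), "features")
})
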