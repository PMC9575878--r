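test_that("generated class counts and shapes follow the design exactly", {
  d <- simulate_binary_data(1000, 30, 10, class_weights = c(0.9, 0.1),
                            seed = 42)
  expect_equal(dim(d$x), c(1000L, 30L))
  expect_equal(sum(d$y == 0L), 900L)
  expect_equal(sum(d$y == 1L), 100L)
  expect_equal(sum(d$informative), 10L)
  expect_false(anyNA(d$x))
})

test_that("identical generator settings give bit-identical datasets", {
  a <- simulate_binary_data(300, 12, 5, class_weights = c(0.7, 0.3),
                            class_sep = 1.5, seed = 7)
  b <- simulate_binary_data(300, 12, 5, class_weights = c(0.7, 0.3),
                            class_sep = 1.5, seed = 7)
  expect_identical(a, b)
})

test_that("with zero informative features every column is uncorrelated noise", {
  d <- simulate_binary_data(1000, 20, 0, seed = 11)
  expect_true(all(abs(point_biserial(d$x, d$y)) < 0.15))
  expect_equal(sum(d$informative), 0L)
})

test_that("strong separation forces near-perfect logistic classification", {
  d <- simulate_binary_data(1000, 30, 10, class_sep = 2, seed = 21)
  sp <- split_dataset(d, 0.25, seed = 21)
  df <- as.data.frame(sp$train)
  fit <- suppressWarnings(glm(class ~ ., binomial, df))
  pred <- as.integer(predict(fit, as.data.frame(sp$test), type = "response") > 0.5)
  expect_gt(f1_score(sp$test$y, pred), 0.9)
})

test_that("informative columns carry more label signal than noise columns", {
  for (s in 1:10) {
    d <- simulate_binary_data(500, 16, 6, class_sep = 1, seed = 100 + s)
    r <- abs(point_biserial(d$x, d$y))
    expect_gt(mean(r[d$informative]), mean(r[!d$informative]))
  }
})

test_that("generator validates its inputs", {
  expect_error(simulate_binary_data(100, 5, 6, seed = 1), "n_informative")
  expect_error(simulate_binary_data(100, 5, 2, class_weights = c(0.5, 0.4)),
               "class_weights")
  expect_error(simulate_binary_data(100, 5, 2, class_sep = -1), "class_sep")
})

test_that("stratified split keeps the imbalance of the full data", {
  # 267 samples at 79.4%:20.6%, as in the heart-imaging dataset geometry
  d <- simulate_binary_data(267, 5, 2, class_weights = c(0.794, 0.206),
                            seed = 3)
  sp <- split_dataset(d, 0.25, stratify = TRUE, seed = 3)
  expect_equal(nrow(sp$test$x), 67L)  # round(267 * 0.25)
  expect_true(sum(sp$test$y == 1L) %in% 13:14)
  # partition identity: union of parts restores the dataset
  idx <- c(sp$train_idx, sp$test_idx)
  expect_setequal(idx, seq_len(267))
  restored <- rbind(sp$train$x, sp$test$x)[order(idx), ]
  expect_equal(restored, d$x)
  expect_equal(c(sp$train$y, sp$test$y)[order(idx)], d$y)
})

test_that("splitting is deterministic under a fixed seed", {
  d <- simulate_binary_data(120, 4, 2, seed = 5)
  s1 <- split_dataset(d, 0.25, seed = 99)
  s2 <- split_dataset(d, 0.25, seed = 99)
  expect_identical(s1$test_idx, s2$test_idx)
})

test_that("degenerate splits are refused", {
  d <- simulate_binary_data(40, 3, 1, class_weights = c(0.95, 0.05), seed = 2)
  expect_error(split_dataset(d, 0.05, seed = 1), "absent")
})
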