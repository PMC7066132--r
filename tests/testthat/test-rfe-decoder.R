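test_that("leave-run-out folds partition trials and validate classes", {
  nl <- null_labels(4, 8)
  folds <- leave_run_out_folds(nl$labels, nl$runs)
  expect_length(folds, 4L)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(tests), seq_along(nl$labels))
  for (f in folds) expect_length(intersect(f$train, f$test), 0L)

  f2 <- leave_run_out_folds(rep(c("a", "b"), 4), rep(1:2, each = 4))
  expect_length(f2, 2L)

  expect_error(leave_run_out_folds(c("a", "a", "b", "b"), c(1, 1, 2, 2)),
               "both classes")
  expect_error(leave_run_out_folds(rep(c("a", "b"), 2), rep(1, 4)),
               "2 runs")
})

test_that("the linear margin classifier satisfies its contracts", {
  # linearly separable: perfect training accuracy, weight along the
  # class-mean difference
  x <- rbind(c(1, 0), c(1.2, 0.1), c(-1, 0), c(-1.1, -0.1))
  y <- c("a", "a", "b", "b")
  fit <- train_linear_margin(x, y)
  expect_equal(as.character(predict(fit, x)), y)
  dirn <- colMeans(x[1:2, ]) - colMeans(x[3:4, ])
  cosang <- sum(fit$weights * dirn) /
    sqrt(sum(fit$weights^2) * sum(dirn^2))
  expect_gt(cosang, 0.95)

  # flipping all labels flips the weight sign
  fit2 <- train_linear_margin(x, c("b", "b", "a", "a"))
  expect_equal(fit2$weights, -fit$weights, tolerance = 1e-8)

  expect_error(train_linear_margin(matrix(1, 4, 3), y), "degenerate")
  expect_error(train_linear_margin(x, c("a", "b", "c", "a")), "2 classes")

  # uninformative features: cross-validated accuracy near 0.5
  set.seed(15)
  accs <- replicate(30, {
    xr <- matrix(rnorm(100 * 5), 100, 5)
    yr <- rep(c("a", "b"), 50)
    fitr <- train_linear_margin(xr[1:60, ], yr[1:60])
    mean(as.character(predict(fitr, xr[61:100, ])) == yr[61:100])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("mask-restricted smoothing follows the neighborhood definition", {
  co <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1:3))
  expect_equal(smooth_weight_map(rep(2.5, 27), co), rep(2.5, 27))

  w <- rep(0, 27); w[14] <- 27   # center voxel of the 3x3x3 block
  sm <- smooth_weight_map(w, co)
  # direct enumeration oracle: mean over each voxel's in-mask neighborhood
  oracle <- vapply(seq_len(27), function(i) {
    nb <- which(abs(co[, 1] - co[i, 1]) <= 1 & abs(co[, 2] - co[i, 2]) <= 1 &
                  abs(co[, 3] - co[i, 3]) <= 1)
    mean(w[nb])
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)

  # isolated voxel keeps its own value
  sm2 <- smooth_weight_map(c(5, 1), rbind(c(1, 1, 1), c(9, 9, 9)))
  expect_equal(sm2, c(5, 1))
})

test_that("RFE follows the ceil elimination schedule with nested survivors", {
  set.seed(20)
  nl <- null_labels(4, 8)
  x <- matrix(rnorm(32 * 100), 32, 100)
  co <- speechmvpa:::.index_to_coord(1:100, c(5, 5, 4))
  cfg <- rfe_config(rng_seed = 2)
  rfe <- withr::with_seed(2, rfe_iterate(x, nl$labels, co, cfg))
  counts <- vapply(rfe$survivors, length, integer(1))
  expect_equal(counts, elimination_schedule(100, 0.3, 10))
  for (k in 2:length(rfe$survivors)) {
    expect_true(all(rfe$survivors[[k]] %in% rfe$survivors[[k - 1]]))
  }

  # a single-voxel ROI admits no elimination: one iteration, itself
  rfe1 <- withr::with_seed(3, rfe_iterate(x[, 1, drop = FALSE], nl$labels,
                                          co[1, , drop = FALSE], cfg))
  expect_equal(rfe1$survivors, list(1L))
})

test_that("RFE survivors are enriched for planted informative voxels", {
  set.seed(44)
  nl <- null_labels(4, 10)
  hits <- replicate(10, {
    x <- matrix(rnorm(40 * 100), 40, 100)
    informative <- 1:10
    x[nl$labels == "a", informative] <- x[nl$labels == "a", informative] + 1
    co <- speechmvpa:::.index_to_coord(1:100, c(5, 5, 4))
    cfg <- rfe_config(n_iterations = 5, splits_per_elimination = 2,
                      n_nested_splits = 10, rng_seed = sample.int(1e6, 1))
    rfe <- rfe_iterate(x, nl$labels, co, cfg)
    final <- rfe$survivors[[length(rfe$survivors)]]
    precision <- mean(final %in% informative)
    precision > 0.1               # prevalence is 10/100
  })
  expect_gte(mean(hits), 0.9)
})

test_that("decode_roi is deterministic and perfect on separable patterns", {
  set.seed(5)
  nl <- null_labels(4, 8)
  x <- matrix(rnorm(32 * 30), 32, 30)
  x[nl$labels == "a", 1:10] <- x[nl$labels == "a", 1:10] + 5
  co <- speechmvpa:::.index_to_coord(1:30, c(5, 3, 2))
  cfg <- rfe_config(n_iterations = 3, splits_per_elimination = 2,
                    n_nested_splits = 6, rng_seed = 11)
  res <- decode_roi(x, nl$labels, nl$runs, 1:30, co, cfg)
  expect_equal(res$final_accuracy, 1)
  res2 <- decode_roi(x, nl$labels, nl$runs, 1:30, co, cfg)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$survivors, res2$survivors)
  expect_error(decode_roi(x, nl$labels, nl$runs, integer(0), co, cfg),
               "empty")
})

test_that("with elimination disabled the decoder equals plain CV", {
  set.seed(9)
  nl <- null_labels(4, 8)
  x <- matrix(rnorm(32 * 12), 32, 12)
  x[nl$labels == "a", 1:4] <- x[nl$labels == "a", 1:4] + 0.8
  co <- speechmvpa:::.index_to_coord(1:12, c(4, 3, 1))
  cfg <- rfe_config(n_iterations = 1, elim_fraction = 0,
                    splits_per_elimination = 1, n_nested_splits = 1,
                    rng_seed = 4)
  res <- decode_roi(x, nl$labels, nl$runs, 1:12, co, cfg)
  # reference: plain leave-run-out CV of the base classifier
  folds <- leave_run_out_folds(nl$labels, nl$runs)
  ref <- mean(vapply(folds, function(f) {
    fit <- train_linear_margin(x[f$train, ], nl$labels[f$train])
    mean(as.character(predict(fit, x[f$test, ])) == nl$labels[f$test])
  }, numeric(1)))
  expect_equal(res$final_accuracy, ref)
})

test_that("permutation null has the requested length and inflated mean", {
  set.seed(2)
  nl <- null_labels(4, 8)
  x <- matrix(rnorm(32 * 40), 32, 40)
  co <- speechmvpa:::.index_to_coord(1:40, c(5, 4, 2))
  cfg <- rfe_config(n_iterations = 3, splits_per_elimination = 2,
                    n_nested_splits = 6, n_permutations = 8, rng_seed = 6)
  nul <- permutation_null(x, nl$labels, nl$runs, 1:40, co, cfg)
  expect_length(nul$accuracies, 8L)
  expect_gt(nul$chance_level, 0.5)   # max-over-iterations inflation
  cfg1 <- cfg; cfg1$n_permutations <- 1L
  expect_length(permutation_null(x, nl$labels, nl$runs, 1:40, co,
                                 cfg1)$accuracies, 1L)
})

test_that("group ROI statistics flag only genuinely above-chance ROIs", {
  # accuracies identical to chance: nothing significant
  tab0 <- expand.grid(roi = paste0("r", 1:5), subject = 1:6)
  tab0$final_accuracy <- 0.6
  tab0$chance <- 0.6
  g0 <- group_roi_stats(tab0)
  expect_false(any(g0$significant))

  set.seed(13)
  tab <- expand.grid(roi = paste0("r", 1:6), subject = 1:10)
  tab$chance <- 0.55 + rnorm(nrow(tab), sd = 0.02)
  tab$final_accuracy <- tab$chance + rnorm(nrow(tab), sd = 0.03) +
    ifelse(tab$roi == "r3", 0.15, 0)
  g <- group_roi_stats(tab)
  expect_true(g$significant[g$roi == "r3"])
  expect_error(group_roi_stats(tab[-1, ]), "subject sets differ")
})
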