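# Training protocol: schedules, clipping, resampling, folds, splits, and the
# reproducibility of the loop itself.

test_that("learning-rate staircase reproduces the published schedules", {
  mitbih <- train_config("mitbih")
  expect_equal(lr_schedule(10, mitbih), 1e-3)
  expect_equal(lr_schedule(25, mitbih), 1e-4)
  expect_equal(lr_schedule(45, mitbih), 1e-5)
  ptb <- train_config("ptb")
  expect_equal(lr_schedule(0, ptb), 1e-3)
  expect_equal(lr_schedule(50, ptb), 1e-4)
  expect_equal(lr_schedule(130, ptb), 1e-5)
  flat <- train_config("synthetic", milestones = integer(0))
  expect_equal(lr_schedule(29, flat), 1e-3)
  expect_error(lr_schedule(60, mitbih), "epoch")
  expect_error(train_config("mitbih", milestones = c(40, 20)), "increasing")
  expect_error(train_config("mitbih", milestones = c(20, 60)), "epochs")
})

test_that("gradient clipping rescales to the exact global norm", {
  cl <- clip_gradients(c(3, 4), 0.001)
  expect_equal(cl$grads, c(0.0006, 0.0008), tolerance = 1e-12)
  expect_equal(sqrt(sum(cl$grads^2)), 0.001, tolerance = 1e-15)
  expect_equal(cl$scale, 0.001 / 5)
  small <- c(3e-4, 4e-4)
  expect_identical(clip_gradients(small, 0.001)$grads, small)
  # list structure is preserved and jointly clipped
  gl <- list(a = matrix(1:4, 2), b = c(-2, 2))
  cl2 <- clip_gradients(gl, 0.001)
  expect_equal(sqrt(sum(unlist(cl2$grads)^2)), 0.001, tolerance = 1e-12)
  expect_equal(cl2$grads$a / gl$a, matrix(rep(cl2$scale, 4), 2))
  expect_error(clip_gradients(c(1, NaN), 0.001), "non-finite")
})

test_that("post-clip norm never exceeds the threshold on random vectors", {
  set.seed(43)
  for (i in 1:1000) {
    g <- rnorm(sample(1:20, 1), sd = 10^runif(1, -5, 1))
    out <- clip_gradients(g, 0.001)
    expect_lte(sqrt(sum(out$grads^2)), 0.001 + 1e-12)
    if (sqrt(sum(g^2)) <= 0.001) expect_identical(out$grads, g)
  }
})

test_that("oversampling balances classes at the majority count", {
  ds <- make_beat_dataset(c(N = 70L, S = 3L, V = 5L, F = 1L, Q = 2L),
                          "five_class", seed = 1)
  os <- oversample(ds, seed = 2)
  expect_equal(as.vector(table(os$labels)), rep(70L, 5))
  expect_equal(length(os$labels), 350L)
  # already balanced input comes back as a permutation
  bal <- make_beat_dataset(rep(5L, 5), "five_class", seed = 3)
  ob <- oversample(bal, seed = 4)
  expect_equal(sort(rowSums(ob$beats)), sort(rowSums(bal$beats)))
  # different seeds give different resampled multisets
  o1 <- oversample(ds, seed = 5)
  o2 <- oversample(ds, seed = 6)
  expect_false(identical(sort(rowSums(o1$beats)), sort(rowSums(o2$beats))))
  empty <- beat_dataset(matrix(0, 0, 187), integer(0))
  expect_error(oversample(empty), "empty")
})

test_that("stratified folds partition the data with balanced class counts", {
  labels <- rep(0:4, each = 20)
  fp <- make_folds(labels, 5, seed = 7)
  expect_s3_class(fp, "fold_plan")
  expect_equal(sort(unique(fp$assignments)), 1:5)
  for (k in 1:5) {
    fold_labels <- labels[fp$assignments == k]
    expect_equal(as.vector(table(fold_labels)), rep(4L, 5))
  }
  # partition: every index in exactly one fold
  expect_length(fp$assignments, 100L)
  expect_warning(make_folds(labels, 1, seed = 1), "single fold")
  expect_error(make_folds(c(0, 0, 1), 2, seed = 1), "fewer than k")
})

test_that("uneven classes split across folds within one sample of ideal", {
  set.seed(8)
  labels <- sample(0:2, 103, replace = TRUE, prob = c(.6, .3, .1))
  fp <- make_folds(labels, 4, seed = 9)
  for (cl in 0:2) {
    per_fold <- table(factor(fp$assignments[labels == cl], levels = 1:4))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
})

test_that("holdout split preserves sizes and class ratios", {
  labels <- rep(0:1, c(800, 200))
  sp <- split_holdout(labels, c(0.75, 0.10, 0.15), seed = 10)
  expect_equal(length(sp$train), 750L)
  expect_equal(length(sp$val), 100L)
  expect_equal(length(sp$test), 150L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))
  # per-class ratios held within one sample
  for (cl in 0:1) {
    n_cl <- sum(labels == cl)
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.75 * n_cl), 1)
    expect_lte(abs(sum(labels[sp$test] == cl) - 0.15 * n_cl), 1)
  }
})

test_that("training is bitwise reproducible and respects the clip ceiling", {
  ds <- make_beat_dataset(rep(12L, 5), "five_class", seed = 20)
  cfg <- train_config("synthetic", epochs = 3L, batch_size = 16L, seed = 21,
                      milestones = integer(0))
  mc <- tiny_model_config(input_len = 187L, n_classes = 5L)
  f1 <- train_model(build_model(mc, seed = 1), ds, NULL, cfg)
  f2 <- train_model(build_model(mc, seed = 1), ds, NULL, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(all(f1$history$max_grad_norm <= 0.001 + 1e-12))
  # learning rate column follows the schedule
  expect_equal(f1$history$lr, rep(1e-3, 3))
})

test_that("a small model overfits a separable synthetic training set", {
  ds <- make_beat_dataset(rep(20L, 5), "five_class", noise_sd = 0.01, seed = 22)
  cfg <- train_config("synthetic", epochs = 25L, batch_size = 10L, seed = 23,
                      milestones = integer(0))
  mc <- model_config(input_len = 187L, stem_filters = 8L,
                     block_filters = c(16L, 16L, 32L, 32L), evo_groups = 4L,
                     head_hidden = 16L)
  fit <- train_model(build_model(mc, seed = 2), ds, NULL, cfg)
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.95)
})

test_that("validation tracking selects the best checkpoint", {
  ds <- make_beat_dataset(rep(15L, 5), "five_class", seed = 24)
  va <- make_beat_dataset(rep(5L, 5), "five_class", seed = 25)
  cfg <- train_config("synthetic", epochs = 4L, batch_size = 25L, seed = 26,
                      milestones = integer(0))
  mc <- tiny_model_config(input_len = 187L, n_classes = 5L)
  fit <- train_model(build_model(mc, seed = 3), ds, va, cfg)
  expect_false(any(is.na(fit$history$val_acc)))
  best <- max(fit$history$val_acc)
  ev <- ecgnet:::eval_on(fit$model, va, cfg)
  expect_equal(ev$acc, best, tolerance = 1e-12)
})

test_that("repeated runs report mean and spread over distinct seeds", {
  ds <- make_beat_dataset(rep(14L, 5), "five_class", seed = 27)
  cfg <- train_config("synthetic", epochs = 2L, batch_size = 35L, seed = 28,
                      milestones = integer(0), split = c(0.6, 0.2, 0.2))
  mc <- tiny_model_config(input_len = 187L, n_classes = 5L)
  rr <- run_repeated(ds, mc, cfg, repeats = 2L)
  expect_length(rr$test_accs, 2L)
  expect_true(is.finite(rr$mean_test_acc))
  expect_true(is.finite(rr$sd_test_acc))
})
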