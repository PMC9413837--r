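test_that("fold plans partition trials without leakage", {
  for (case in list(list(scheme = "deap5", n = 40L, k = 5L, test = 8L,
                         val = 8L),
                    list(scheme = "dreamer6", n = 18L, k = 6L, test = 3L,
                         val = 3L))) {
    plan <- make_folds(case$n, case$scheme, seed = 3)
    expect_identical(plan$k, case$k)
    all_test <- integer()
    for (f in plan$folds) {
      expect_length(f$test, case$test)
      expect_length(f$train, case$n - case$test)
      expect_length(f$val, case$val)
      expect_length(intersect(f$train, f$test), 0L)
      expect_true(all(f$val %in% f$train))   # validation drawn from train
      all_test <- c(all_test, f$test)
    }
    expect_identical(sort(all_test), seq_len(case$n))  # disjoint cover
  }
  expect_error(make_folds(30, "deap5"), "expects 40 trials")
})

test_that("the 7-emotion scheme balances classes across folds", {
  labels <- rep(0:6, each = 4)
  plan <- make_folds(28, "mped4", labels = labels, seed = 11)
  expect_identical(plan$k, 4L)
  all_test <- integer()
  for (f in plan$folds) {
    expect_length(f$test, 7L)
    # exactly one clip of every emotion in each test fold
    expect_identical(sort(labels[f$test]), 0:6)
    expect_identical(sort(labels[f$val]), 0:6)
    expect_length(f$train, 21L)
    expect_length(intersect(f$train, f$test), 0L)
    all_test <- c(all_test, f$test)
  }
  expect_identical(sort(all_test), 1:28)
  expect_error(make_folds(28, "mped4", labels = rep(0:3, 7)),
               "7 classes")
})

test_that("fold plans are reproducible from their seed", {
  p1 <- make_folds(18, "dreamer6", seed = 42)
  p2 <- make_folds(18, "dreamer6", seed = 42)
  p3 <- make_folds(18, "dreamer6", seed = 43)
  expect_identical(p1, p2)
  expect_false(identical(p1$folds, p3$folds))
})

test_that("evaluation identities hold: accuracy, confusion, forced chance", {
  seg <- tiny_separable_segments(n_per_class = 8)
  cfg <- model_config(C = 2, T = 64, n_classes = 2, F1 = 2, F2 = 4,
                      lstm_units = c(4, 3), temporal_kernel = 8,
                      separable_kernel = 4, pool1 = 4, pool2 = 8,
                      seed = 5)
  model <- build_model(cfg)
  ev <- evaluate(model, seg)
  expect_equal(ev$accuracy,
               sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_identical(sum(ev$confusion), length(seg$labels))
  # constant-logit model always answers class 0 -> exactly 0.5 on a
  # balanced set; confusion has one empty predicted column
  model$params$dense$W[] <- 0
  model$params$dense$b <- c(10, 0)
  ev0 <- evaluate(model, seg)
  expect_equal(ev0$accuracy, 0.5)
  expect_identical(unname(ev0$confusion[, 2]), c(0L, 0L))
})

test_that("training on separable segments is seeded, logged and learns", {
  seg <- tiny_separable_segments()
  cfg <- model_config(C = 2, T = 64, n_classes = 2, F1 = 4, F2 = 8,
                      lstm_units = c(8, 4), temporal_kernel = 16,
                      separable_kernel = 8, dropout_p = 0.25, seed = 5)
  tc <- train_config(epochs = 12, batch_size = 16, seed = 6)
  r1 <- train_fold(build_model(cfg), seg, val = seg, tc = tc)
  expect_identical(nrow(r1$history), 12L)       # one row per epoch
  expect_gt(tail(r1$history$acc, 1), 0.95)      # drives training accuracy
  expect_false(any(is.na(r1$history$val_acc)))
  # bit-identical reruns under the same seeds
  r2 <- train_fold(build_model(cfg), seg, val = seg, tc = tc)
  expect_identical(r1$history$loss[1], r2$history$loss[1])
  expect_equal(r1$model$params$dense$W, r2$model$params$dense$W)
  expect_error(train_fold(build_model(cfg),
                          segment_set(array(0, c(0, 2, 64)), integer(),
                                      integer(), 64, 2L), tc = tc),
               "empty training split")
})

test_that("cross-validation aggregates exactly and never leaks trials", {
  spec <- synthetic_spec("generic", n_trials = 8, n_channels = 3,
                         test_s = 6, baseline_s = 1, fs = 32,
                         alpha_effect = 4, seed = 71)
  rec <- generate_recording_set(spec)
  tc <- train_config(epochs = 2, seed = 19)
  mc <- model_config(C = 3, T = 32, n_classes = 2, F1 = 2, F2 = 4,
                     lstm_units = c(6, 4), temporal_kernel = 8,
                     separable_kernel = 4, pool1 = 4, pool2 = 8, seed = 19)
  cv <- run_subject_dependent_cv(rec, mc = mc, tc = tc, scheme = "generic",
                                 k = 4)
  expect_equal(cv$mean, mean(cv$fold_accuracy))
  expect_equal(cv$sd, sd(cv$fold_accuracy))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_identical(sum(cv$confusion), 8L * 6L)  # every segment tested once
  seg <- preprocess_recording(rec)
  for (f in cv$fold_plan$folds) {
    tr_idx <- e2ennet:::segments_of_trials(seg, f$train)
    te_idx <- e2ennet:::segments_of_trials(seg, f$test)
    expect_length(intersect(seg$trial_index[tr_idx],
                            seg$trial_index[te_idx]), 0L)
  }
})

test_that("shared seeds give every ablation variant identical folds", {
  spec <- synthetic_spec("generic", n_trials = 6, n_channels = 2,
                         test_s = 4, baseline_s = 0, fs = 32,
                         alpha_effect = 4, seed = 72)
  rec <- generate_recording_set(spec)
  tc <- train_config(epochs = 1, seed = 23)
  tab <- run_ablation(rec, variants = c("full", "no_lstm"), tc = tc,
                      scheme = "generic", k = 3)
  expect_identical(nrow(tab), 2L)
  res <- attr(tab, "results")
  expect_identical(res$full$fold_plan$folds, res$no_lstm$fold_plan$folds)
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
})
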