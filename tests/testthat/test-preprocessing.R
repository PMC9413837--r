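test_that("per-second baseline mean matches the block-mean oracle", {
  # worked example: fs = 2, baseline [1 2 | 3 4] -> mean second [2 3]
  expect_equal(compute_baseline_mean(matrix(c(1, 2, 3, 4), 1), 2),
               matrix(c(2, 3), 1))
  expect_equal(compute_baseline_mean(matrix(0, 32, 384), 128),
               matrix(0, 32, 128))
  e2ennet:::with_seed(21, {
    b <- matrix(rnorm(32 * 384), 32)
    got <- compute_baseline_mean(b, 128)
    oracle <- matrix(0, 32, 128)
    for (blk in 0:2) oracle <- oracle + b[, blk * 128 + 1:128]
    oracle <- oracle / 3
    expect_equal(got, oracle, tolerance = 1e-12)
  })
  expect_error(compute_baseline_mean(matrix(0, 2, 5), 2), "multiple of fs")
  expect_error(compute_baseline_mean(matrix(0, 2, 0), 2), "empty baseline")
})

test_that("baseline removal is per-second subtraction", {
  e2ennet:::with_seed(22, {
    s <- matrix(rnorm(14 * 7680), 14)
    bm <- matrix(rnorm(14 * 128), 14)
    # additive inverse: removing a tiled baseline recovers the signal
    tiled <- bm[, rep(1:128, 60)]
    expect_equal(remove_baseline(s + tiled, bm, 128), s, tolerance = 1e-12)
    # zero baseline is the identity
    expect_equal(remove_baseline(s, matrix(0, 14, 128), 128), s)
    # explicit per-second loop oracle
    test <- matrix(rnorm(14 * 7680), 14)
    oracle <- test
    for (sec in 0:59) oracle[, sec * 128 + 1:128] <-
      test[, sec * 128 + 1:128] - bm
    expect_equal(remove_baseline(test, bm, 128), oracle, tolerance = 1e-12)
  })
  expect_error(remove_baseline(matrix(0, 2, 10), matrix(0, 2, 4), 4),
               "not a multiple")
  expect_error(remove_baseline(matrix(0, 2, 8), matrix(0, 3, 4), 4),
               "channel mismatch")
})

test_that("window slicing yields floor(J/window) ordered segments", {
  e2ennet:::with_seed(23, {
    x60 <- matrix(rnorm(4 * 60 * 128), 4)
    expect_identical(dim(slice_windows(x60, 128)), c(60L, 4L, 128L))
    x120 <- matrix(rnorm(2 * 120 * 128), 2)
    expect_identical(dim(slice_windows(x120, 128))[1], 120L)
    # a single window is the input itself
    x1 <- matrix(rnorm(3 * 16), 3)
    w <- slice_windows(x1, 16)
    expect_identical(dim(w), c(1L, 3L, 16L))
    expect_equal(w[1, , ], x1)
    # concatenating the windows reproduces the covered prefix
    x <- matrix(rnorm(2 * 37), 2)
    ws <- slice_windows(x, 8)
    rebuilt <- do.call(cbind, lapply(seq_len(dim(ws)[1]),
                                     function(i) ws[i, , ]))
    expect_equal(rebuilt, x[, 1:32])
  })
  expect_error(slice_windows(matrix(0, 1, 4), 8), "shorter than one window")
  expect_error(slice_windows(matrix(0, 1, 16), 8, window_s = 0), "positive")
})

test_that("worked fixtures preprocess to hand-checkable values", {
  fx <- generate_worked_fixtures()
  seg <- preprocess_recording(fx$constant)
  # constant 3 with constant baseline 1 -> every preprocessed sample is 2
  expect_true(all(abs(seg$segments - 2) < 1e-12))
  # 5 s of test span -> 5 windows per trial
  expect_identical(dim(seg$segments), c(4L * 5L, 2L, 8L))
  expect_identical(seg$labels, rep(c(0L, 1L, 0L, 1L), each = 5))
  expect_identical(seg$trial_index, rep(1:4, each = 5))
  # deterministic: regenerating gives identical data
  fx2 <- generate_worked_fixtures()
  expect_identical(fx2$random$data, fx$random$data)
})

test_that("segment counts follow n_trials * floor(test_s) for random layouts", {
  e2ennet:::with_seed(24, {
    for (i in 1:4) {
      nt <- sample(2:6, 1); nc <- sample(1:4, 1)
      ts <- sample(3:9, 1); bs <- sample(0:2, 1); fs <- 8L
      spec <- synthetic_spec("generic", n_trials = nt, n_channels = nc,
                             test_s = ts, baseline_s = bs, fs = fs,
                             seed = sample(1e6, 1))
      seg <- preprocess_recording(generate_recording_set(spec))
      expect_identical(dim(seg$segments), c(nt * ts, nc, fs))
      expect_identical(as.integer(table(seg$trial_index)),
                       rep(ts, nt))
      # each segment inherits its source trial's label
      lab <- recording_labels(generate_recording_set(spec))
      expect_identical(seg$labels, lab[seg$trial_index])
    }
  })
})
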