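#' Per-second average of a baseline signal
#'
#' The pre-stimulus baseline of a trial (`channels x L` samples, with
#' `L = fs * T2` for an integer number of baseline seconds `T2`) is cut into
#' `T2` one-second blocks and averaged block-wise, giving the mean baseline
#' second: a `channels x fs` matrix.
#'
#' @param baseline numeric matrix, `channels x L`.
#' @param fs sampling rate in Hz.
#' @return `channels x fs` matrix of per-second baseline means.
#' @export
compute_baseline_mean <- function(baseline, fs) {
  assert_that(is.matrix(baseline), "baseline must be a channels x L matrix")
  L <- ncol(baseline)
  fs <- as.integer(fs)
  assert_that(L %% fs == 0,
              "baseline length (%d) is not a multiple of fs (%d)", L, fs)
  t2 <- L %/% fs
  assert_that(t2 >= 1, "empty baseline: nothing to average")
  # mean over the T2 blocks: reshape (M, fs, T2) and average the 3rd axis
  m <- nrow(baseline)
  arr <- array(baseline, dim = c(m, fs, t2))
  out <- arr[, , 1, drop = FALSE]
  if (t2 > 1) for (i in 2:t2) out <- out + arr[, , i, drop = FALSE]
  matrix(out / t2, nrow = m, ncol = fs)
}

#' Subtract the mean baseline second from every second of a test signal
#'
#' The test signal is split into non-overlapping 1-s slices; the per-second
#' baseline mean is subtracted from each slice and the slices are
#' re-concatenated in order.
#'
#' @param test numeric matrix, `channels x J` with `J` a multiple of `fs`.
#' @param baseline_mean `channels x fs` matrix from [compute_baseline_mean()].
#' @param fs sampling rate in Hz.
#' @return matrix of the same shape as `test`.
#' @export
remove_baseline <- function(test, baseline_mean, fs) {
  fs <- as.integer(fs)
  assert_that(is.matrix(test) && is.matrix(baseline_mean),
              "test and baseline_mean must be matrices")
  assert_that(ncol(baseline_mean) == fs,
              "baseline_mean has width %d, expected fs = %d",
              ncol(baseline_mean), fs)
  assert_that(nrow(test) == nrow(baseline_mean),
              "channel mismatch: test %d vs baseline %d",
              nrow(test), nrow(baseline_mean))
  J <- ncol(test)
  assert_that(J %% fs == 0,
              "test length (%d) is not a multiple of fs (%d)", J, fs)
  # tile the baseline second across the full duration and subtract
  reps <- J %/% fs
  tiled <- baseline_mean[, rep(seq_len(fs), reps), drop = FALSE]
  test - tiled
}

#' Slice a continuous signal into non-overlapping windows
#'
#' @param signal numeric matrix, `channels x J`.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1 s, i.e. `T = fs`
#'   samples per window).
#' @return array `n x channels x (fs*window_s)` of the
#'   `n = floor(J / (fs*window_s))` in-order windows; trailing samples that
#'   do not fill a window are discarded.
#' @export
slice_windows <- function(signal, fs, window_s = 1) {
  assert_that(is.matrix(signal), "signal must be a channels x J matrix")
  assert_that(window_s > 0, "window_s must be positive")
  w <- as.integer(round(fs * window_s))
  J <- ncol(signal)
  assert_that(J >= w, "signal (%d samples) shorter than one window (%d)",
              J, w)
  n <- J %/% w
  m <- nrow(signal)
  # (M, w*n) -> (M, w, n) -> (n, M, w)
  arr <- array(signal[, seq_len(n * w), drop = FALSE], dim = c(m, w, n))
  aperm(arr, c(3, 1, 2))
}

#' Labelled 1-s segments of a recording set
#'
#' Applies the full preprocessing chain to every trial: if the recording has
#' a baseline, the first `baseline_s` seconds are split off, averaged per
#' second and subtracted from every second of the remaining test signal;
#' the (baseline-removed) test signal is then sliced into non-overlapping
#' windows. Labels are propagated from trials to all their segments.
#'
#' @param rec a [recording_set()].
#' @param window_s window length in seconds (default 1).
#' @param dimension rating dimension used to derive 2-class labels when the
#'   recording carries continuous ratings.
#' @param threshold binarisation threshold; defaults to the dialect's
#'   convention (5 for deap, 3 for dreamer, scale midpoint otherwise).
#' @param standardize optionally z-score each channel across a trial's test
#'   signal after baseline removal (off by default; the raw baseline-removed
#'   values are what the network consumes).
#' @return an object of class `segment_set` with elements
#'   `segments` (`n_segments x channels x T`), `labels`, `trial_index`,
#'   `fs`, `T`, `n_classes`.
#' @export
preprocess_recording <- function(rec, window_s = 1, dimension = "valence",
                                 threshold = NULL, standardize = FALSE) {
  stopifnot(inherits(rec, "recording_set"))
  labels <- recording_labels(rec, dimension, threshold)
  fs <- rec$fs
  w <- as.integer(round(fs * window_s))
  nb <- rec$baseline_s * fs
  nt <- n_trials(rec)

  per_trial <- vector("list", nt)
  for (tr in seq_len(nt)) {
    x <- rec$data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (nb > 0) {
      bm <- compute_baseline_mean(x[, seq_len(nb), drop = FALSE], fs)
      test <- remove_baseline(x[, -seq_len(nb), drop = FALSE], bm, fs)
    } else {
      test <- x
    }
    if (standardize) {
      mu <- rowMeans(test)
      sd <- apply(test, 1, stats::sd)
      sd[sd == 0] <- 1
      test <- (test - mu) / sd
    }
    per_trial[[tr]] <- slice_windows(test, fs, window_s)
  }

  n_per <- vapply(per_trial, function(a) dim(a)[1], integer(1))
  total <- sum(n_per)
  nc <- n_channels(rec)
  segments <- array(0, dim = c(total, nc, w))
  at <- 0L
  for (tr in seq_len(nt)) {
    segments[at + seq_len(n_per[tr]), , ] <- per_trial[[tr]]
    at <- at + n_per[tr]
  }

  n_classes <- if (!is.null(rec$discrete_labels))
    max(rec$discrete_labels) + 1L else 2L

  segment_set(segments,
              labels = rep(labels, n_per),
              trial_index = rep(seq_len(nt), n_per),
              fs = fs, n_classes = n_classes)
}

#' Construct a segment set
#'
#' @param segments array `n_segments x channels x T`.
#' @param labels integer vector of 0-based per-segment classes.
#' @param trial_index integer vector mapping each segment to its source
#'   trial.
#' @param fs sampling rate in Hz.
#' @param n_classes number of classes in the task.
#' @return a `segment_set`.
#' @export
segment_set <- function(segments, labels, trial_index, fs,
                        n_classes = max(labels) + 1L) {
  assert_that(length(dim(segments)) == 3, "segments must be a 3-d array")
  n <- dim(segments)[1]
  assert_that(length(labels) == n && length(trial_index) == n,
              "labels / trial_index must have one entry per segment")
  structure(list(segments = segments, labels = as.integer(labels),
                 trial_index = as.integer(trial_index),
                 fs = as.integer(fs), T = dim(segments)[3],
                 n_classes = as.integer(n_classes)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<segment_set> %d segments x %d channels x %d samples @ %d Hz, %d classes\n",
    d[1], d[2], d[3], x$fs, x$n_classes))
  invisible(x)
}

# Subset a segment_set by segment indices, keeping metadata consistent.
subset_segments <- function(seg, idx) {
  segment_set(seg$segments[idx, , , drop = FALSE], seg$labels[idx],
              seg$trial_index[idx], seg$fs, seg$n_classes)
}

# Segment indices whose source trial is in `trials`.
segments_of_trials <- function(seg, trials) {
  which(seg$trial_index %in% trials)
}
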