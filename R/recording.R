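#' EEG recording sets
#'
#' A `recording_set` holds one subject's raw EEG as a
#' `trials x channels x samples` array together with its sampling rate, the
#' duration of the pre-stimulus baseline at the start of every trial, and
#' either continuous affective ratings (valence / arousal / dominance) or
#' discrete emotion labels. Three dataset dialects are built in, matching the
#' public emotion corpora the method was designed for, plus a `generic`
#' dialect for arbitrary layouts:
#'
#' * `deap`: 32 channels, 3 s baseline, ratings on 1--9 (binarisation
#'   threshold 5), 40 trials of 63 s at 128 Hz;
#' * `dreamer`: 14 channels, 1 s baseline, ratings on 1--5 (threshold 3),
#'   18 trials of 61 s at 128 Hz;
#' * `mped`: 62 channels, no baseline, 7 discrete emotion classes
#'   (joy, fun, neutrality, sadness, fear, disgust, anger as classes 0..6),
#'   28 trials of 120 s at 128 Hz.
#'
#' @param data numeric array, `n_trials x n_channels x n_samples`.
#' @param fs sampling rate in Hz.
#' @param baseline_s baseline duration in whole seconds (>= 0) at the start
#'   of every trial.
#' @param ratings optional data frame / named list of per-trial numeric
#'   scores, one element per rating dimension (e.g. `valence`, `arousal`).
#' @param discrete_labels optional integer vector of per-trial 0-based class
#'   labels. Exactly one of `ratings` / `discrete_labels` must be given.
#' @param dialect one of `"deap"`, `"dreamer"`, `"mped"`, `"generic"`.
#' @param subject_id identifier string.
#' @param channels optional character vector of channel names (carried
#'   through, never interpreted).
#'
#' @return an object of class `recording_set`.
#' @export
recording_set <- function(data, fs, baseline_s, ratings = NULL,
                          discrete_labels = NULL, dialect = "generic",
                          subject_id = "s01", channels = NULL) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "`data` must be a 3-d array (trials x channels x samples)")
  dialect <- match.arg(dialect, c("deap", "dreamer", "mped", "generic"))
  fs <- as.integer(fs)
  baseline_s <- as.integer(baseline_s)
  assert_that(fs > 0, "sampling rate must be positive")
  assert_that(baseline_s >= 0, "baseline duration must be >= 0")

  n_trials <- dim(data)[1]
  n_samples <- dim(data)[3]
  assert_that(n_samples %% fs == 0,
              "n_samples (%d) must be a whole number of seconds at fs = %d",
              n_samples, fs)
  assert_that(n_samples / fs > baseline_s,
              "trial shorter than its declared baseline")

  has_r <- !is.null(ratings)
  has_d <- !is.null(discrete_labels)
  assert_that(xor(has_r, has_d),
              "exactly one of `ratings` / `discrete_labels` must be present")

  if (has_r) {
    ratings <- as.data.frame(ratings)
    assert_that(nrow(ratings) == n_trials,
                "ratings rows (%d) != n_trials (%d)", nrow(ratings), n_trials)
  } else {
    discrete_labels <- as.integer(discrete_labels)
    assert_that(length(discrete_labels) == n_trials,
                "discrete_labels length (%d) != n_trials (%d)",
                length(discrete_labels), n_trials)
    assert_that(all(discrete_labels >= 0L),
                "discrete labels must be 0-based non-negative integers")
  }

  rec <- structure(
    list(data = data, fs = fs, baseline_s = baseline_s,
         ratings = ratings, discrete_labels = discrete_labels,
         dialect = dialect, subject_id = as.character(subject_id),
         channels = channels),
    class = "recording_set")
  validate_recording_set(rec)
  rec
}

# Per-dialect layout constraints (channel count, baseline, rating range).
dialect_spec <- function(dialect) {
  switch(dialect,
    deap    = list(n_channels = 32L, baseline_s = 3L, rating_range = c(1, 9),
                   threshold = 5, n_classes = NA_integer_),
    dreamer = list(n_channels = 14L, baseline_s = 1L, rating_range = c(1, 5),
                   threshold = 3, n_classes = NA_integer_),
    mped    = list(n_channels = 62L, baseline_s = 0L, rating_range = NULL,
                   threshold = NA_real_, n_classes = 7L),
    generic = list(n_channels = NA_integer_, baseline_s = NA_integer_,
                   rating_range = NULL, threshold = NA_real_,
                   n_classes = NA_integer_))
}

validate_recording_set <- function(rec) {
  ds <- dialect_spec(rec$dialect)
  nc <- dim(rec$data)[2]
  if (!is.na(ds$n_channels))
    assert_that(nc == ds$n_channels,
                "dialect '%s' expects %d channels, found %d",
                rec$dialect, ds$n_channels, nc)
  if (!is.na(ds$baseline_s))
    assert_that(rec$baseline_s == ds$baseline_s,
                "dialect '%s' expects a %d s baseline, found %d s",
                rec$dialect, ds$baseline_s, rec$baseline_s)
  if (!is.null(ds$rating_range)) {
    assert_that(!is.null(rec$ratings),
                "dialect '%s' carries continuous ratings", rec$dialect)
    rng <- ds$rating_range
    ok <- vapply(rec$ratings, function(x) all(x >= rng[1] & x <= rng[2]),
                 logical(1))
    assert_that(all(ok), "dialect '%s' ratings must lie in [%g, %g]",
                rec$dialect, rng[1], rng[2])
  }
  if (!is.na(ds$n_classes)) {
    assert_that(!is.null(rec$discrete_labels),
                "dialect '%s' carries discrete labels", rec$dialect)
    assert_that(all(rec$discrete_labels < ds$n_classes),
                "dialect '%s' has %d classes (0-based labels)",
                rec$dialect, ds$n_classes)
  }
  invisible(rec)
}

#' @export
print.recording_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<recording_set> subject %s, dialect %s\n  %d trials x %d channels x %d samples @ %d Hz (%d s baseline)\n",
    x$subject_id, x$dialect, d[1], d[2], d[3], x$fs, x$baseline_s))
  if (!is.null(x$ratings))
    cat("  ratings:", paste(names(x$ratings), collapse = ", "), "\n")
  else
    cat("  discrete labels:", length(unique(x$discrete_labels)), "classes\n")
  invisible(x)
}

#' Number of trials / channels / test seconds of a recording set
#' @param rec a `recording_set`.
#' @return integer.
#' @export
n_trials <- function(rec) dim(rec$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(rec) dim(rec$data)[2]

#' @rdname n_trials
#' @export
test_seconds <- function(rec) dim(rec$data)[3] %/% rec$fs - rec$baseline_s

#' Binarise continuous affective ratings into High/Low classes
#'
#' Scores strictly greater than the threshold map to High (class 1), all
#' others -- including scores exactly at the threshold -- to Low (class 0).
#' The default thresholds follow the datasets' conventions: 5 on the 1--9
#' scale, 3 on the 1--5 scale.
#'
#' @param ratings a data frame of per-trial scores (as in a
#'   [recording_set()]) or a numeric vector.
#' @param dimension rating dimension name (ignored when `ratings` is already
#'   a vector).
#' @param threshold cut point; High iff score > threshold.
#' @return integer vector of classes, 0 = Low, 1 = High.
#' @export
binarize_labels <- function(ratings, dimension = "valence", threshold = 5) {
  if (is.data.frame(ratings) || is.list(ratings)) {
    assert_that(dimension %in% names(ratings),
                "unknown rating dimension '%s' (have: %s)", dimension,
                paste(names(ratings), collapse = ", "))
    scores <- ratings[[dimension]]
  } else {
    scores <- ratings
  }
  assert_that(is.numeric(scores) && length(scores) > 0,
              "ratings must be numeric")
  as.integer(scores > threshold)
}

# Resolve the per-trial integer labels for a task on a recording set.
recording_labels <- function(rec, dimension = "valence", threshold = NULL) {
  if (!is.null(rec$discrete_labels)) return(rec$discrete_labels)
  if (is.null(threshold)) {
    thr <- dialect_spec(rec$dialect)$threshold
    threshold <- if (is.na(thr)) {
      rng <- range(unlist(rec$ratings))
      mean(rng)
    } else thr
  }
  binarize_labels(rec$ratings, dimension, threshold)
}
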