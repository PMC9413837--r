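#' Specification for a synthetic emotional-EEG recording set
#'
#' Describes a class-conditional generative model of multi-channel EEG with
#' the exact layout of the three supported corpora (or any generic layout).
#' Every trial is the sum of
#'
#' * a per-trial, per-channel constant offset (drawn with standard
#'   deviation `baseline_offset_sd`) covering the whole trial -- the
#'   resting-level drift that per-second baseline subtraction must cancel;
#' * pink (1/f) background noise with standard deviation `pink_sd`,
#'   mimicking the EEG spectrum;
#' * band-limited oscillations: in each canonical band one sinusoid at a
#'   trial-specific frequency inside the band, with channel-specific random
#'   phase, amplitude `osc_amp[band] * sqrt(effect[class, band]) *
#'   spatial_pattern[class, channel]` -- the class information lives in
#'   these band-power multipliers, present only during the post-baseline
#'   test span;
#' * white measurement noise with standard deviation `noise_sd`.
#'
#' Ratings for the 2-class dialects are drawn uniformly from the High or
#' Low side of the dialect's binarisation threshold, so binarising them
#' recovers the planted class exactly.
#'
#' @param dialect `"deap"`, `"dreamer"`, `"mped"` or `"generic"`. The three
#'   corpus dialects force the layout fields to the corpus values
#'   (40x32x(3+60 s), 18x14x(1+60 s), 28x62x120 s, all at 128 Hz).
#' @param n_trials,n_channels,test_s,baseline_s,fs layout of a generic set.
#' @param class_count number of planted classes (2 for rating dialects,
#'   7 for mped).
#' @param effect `class_count x 5` matrix of band-power multipliers
#'   (> 0; 1 = no class-specific signal). Default: all 1 except class 1
#'   ("High"), whose alpha power is multiplied by `alpha_effect`.
#' @param alpha_effect convenience scalar used to build the default
#'   `effect` matrix (default 2).
#' @param spatial_pattern `class_count x n_channels` channel weighting of
#'   the oscillations (default all 1).
#' @param osc_amp length-5 base oscillation amplitude per band.
#' @param baseline_offset_sd,pink_sd,noise_sd component scales (arbitrary
#'   amplitude units).
#' @param seed integer seed; the output is fully determined by it.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(dialect = "generic", n_trials = 12,
                           n_channels = 8, test_s = 20, baseline_s = 1,
                           fs = 128, class_count = 2, effect = NULL,
                           alpha_effect = 2, spatial_pattern = NULL,
                           osc_amp = c(1, 1, 2.5, 0.5, 0.25),
                           baseline_offset_sd = 5,
                           pink_sd = 1, noise_sd = 1, seed = 1L) {
  dialect <- match.arg(dialect, c("deap", "dreamer", "mped", "generic"))
  layout <- switch(dialect,
    deap    = list(n_trials = 40L, n_channels = 32L, test_s = 60L,
                   baseline_s = 3L, fs = 128L, class_count = 2L),
    dreamer = list(n_trials = 18L, n_channels = 14L, test_s = 60L,
                   baseline_s = 1L, fs = 128L, class_count = 2L),
    mped    = list(n_trials = 28L, n_channels = 62L, test_s = 120L,
                   baseline_s = 0L, fs = 128L, class_count = 7L),
    generic = list(n_trials = as.integer(n_trials),
                   n_channels = as.integer(n_channels),
                   test_s = as.integer(test_s),
                   baseline_s = as.integer(baseline_s),
                   fs = as.integer(fs),
                   class_count = as.integer(class_count)))
  if (is.null(effect)) {
    effect <- matrix(1, layout$class_count, 5)
    if (layout$class_count == 2) {
      effect[2, 3] <- alpha_effect              # class High, alpha band
    } else {
      # give every class its own band signature so all are separable
      for (cl in seq_len(layout$class_count))
        if (cl > 1)
          effect[cl, (cl - 2) %% 5 + 1] <- alpha_effect^(1 + (cl - 2) %/% 5)
    }
  }
  assert_that(nrow(effect) == layout$class_count && ncol(effect) == 5,
              "effect must be class_count x 5")
  assert_that(all(effect > 0), "effect multipliers must be positive")
  if (is.null(spatial_pattern))
    spatial_pattern <- matrix(1, layout$class_count, layout$n_channels)
  assert_that(nrow(spatial_pattern) == layout$class_count &&
                ncol(spatial_pattern) == layout$n_channels,
              "spatial_pattern must be class_count x n_channels")
  structure(c(layout,
              list(dialect = dialect, effect = effect,
                   spatial_pattern = spatial_pattern, osc_amp = osc_amp,
                   baseline_offset_sd = baseline_offset_sd,
                   pink_sd = pink_sd, noise_sd = noise_sd,
                   seed = as.integer(seed))),
            class = "synthetic_spec")
}

# Pink (1/f amplitude-slope -1/2, i.e. power slope -1) noise of length n,
# scaled to standard deviation sd. Power below `hp` Hz is removed, as in
# the high-pass-filtered distributions of the public corpora.
pink_noise <- function(n, fs, sd = 1, hp = 1) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                         # two-sided frequency axis
  shape <- numeric(n)
  keep <- f >= hp
  shape[keep] <- 1 / sqrt(f[keep])
  sp <- sp * shape
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s * sd
  x
}

#' Generate a synthetic recording set
#'
#' @param spec a [synthetic_spec()].
#' @return a [recording_set()] with the spec's layout and dialect; fully
#'   determined by `spec$seed`.
#' @export
generate_recording_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    nt <- spec$n_trials; nc <- spec$n_channels; fs <- spec$fs
    n_test <- spec$test_s * fs
    n_base <- spec$baseline_s * fs
    N <- n_base + n_test
    bands <- eeg_bands()

    classes <- sample(rep(seq_len(spec$class_count) - 1L,
                          length.out = nt))
    # one rhythm frequency per band for the whole recording: a subject's
    # oscillation peaks (e.g. the individual alpha frequency) are stable
    # across trials; drawn from the band's interior so the rhythm is
    # unambiguously inside it
    freqs <- vapply(bands, function(b) {
      bw <- b$high - b$low
      stats::runif(1, b$low + 0.25 * bw, b$high - 0.25 * bw)
    }, 0)
    data <- array(0, dim = c(nt, nc, N))
    t_test <- (seq_len(n_test) - 1) / fs
    for (tr in seq_len(nt)) {
      cl <- classes[tr] + 1L
      x <- matrix(stats::rnorm(nc * N, sd = spec$noise_sd), nc, N)
      for (m in seq_len(nc))
        x[m, ] <- x[m, ] + pink_noise(N, fs, spec$pink_sd)
      # constant per-trial offset over the whole trial
      x <- x + stats::rnorm(nc, sd = spec$baseline_offset_sd)
      # class-dependent band oscillations over the test span only. Real
      # rhythms keep a stable frequency but only short-lived phase
      # coherence, and volume conduction spreads a source across channels
      # essentially in phase: the phase is redrawn every second, shared
      # by all channels.
      tt1 <- 2 * pi * (seq_len(fs) - 1) / fs
      for (b in seq_along(bands)) {
        freq <- freqs[b]
        amp <- spec$osc_amp[b] * sqrt(spec$effect[cl, b]) *
          spec$spatial_pattern[cl, ]
        for (sec in seq_len(spec$test_s) - 1L) {
          phase <- stats::runif(1, 0, 2 * pi)
          cols <- n_base + sec * fs + seq_len(fs)
          x[, cols] <- x[, cols] +
            amp %o% sin(phase + freq * tt1)
        }
      }
      data[tr, , ] <- x
    }

    if (spec$class_count == 2 && spec$dialect != "mped") {
      rng <- switch(spec$dialect, deap = c(1, 9), dreamer = c(1, 5),
                    c(1, 9))
      thr <- switch(spec$dialect, deap = 5, dreamer = 3, 5)
      draw <- function(cls) ifelse(
        cls == 1L, stats::runif(length(cls), thr + 0.25, rng[2]),
        stats::runif(length(cls), rng[1], thr - 0.25))
      ratings <- data.frame(valence = draw(classes),
                            arousal = draw(classes),
                            dominance = draw(classes))
      recording_set(data, fs, spec$baseline_s, ratings = ratings,
                    dialect = spec$dialect, subject_id = "synthetic")
    } else {
      recording_set(data, fs, spec$baseline_s,
                    discrete_labels = classes, dialect = spec$dialect,
                    subject_id = "synthetic")
    }
  })
}

#' Tiny deterministic fixtures with hand-checkable arithmetic
#'
#' A bundle of miniature recording sets whose preprocessing results can be
#' verified by hand: a constant-signal set (test value 3, baseline value 1,
#' so every preprocessed sample equals 2), and a small random generic set.
#' Optionally persists both in the HDF5 layout.
#'
#' @param dir optional directory; when given, the fixtures are written as
#'   `constant.h5` and `random.h5` inside it.
#' @return list with `constant` and `random` recording sets (and `paths`
#'   when written).
#' @export
generate_worked_fixtures <- function(dir = NULL) {
  fs <- 8L
  nt <- 4L; nc <- 2L
  n <- fs * 6L                                  # 1 s baseline + 5 s test
  data <- array(3, dim = c(nt, nc, n))
  data[, , seq_len(fs)] <- 1                    # baseline second
  constant <- recording_set(data, fs, baseline_s = 1,
                            ratings = data.frame(valence = c(1, 9, 1, 9)),
                            dialect = "generic", subject_id = "fix-const")
  random <- with_seed(20260101L, {
    arr <- array(stats::rnorm(nt * nc * n), dim = c(nt, nc, n))
    recording_set(arr, fs, baseline_s = 1,
                  ratings = data.frame(valence = c(2, 8, 8, 2)),
                  dialect = "generic", subject_id = "fix-rand")
  })
  out <- list(constant = constant, random = random)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(constant = file.path(dir, "constant.h5"),
               random = file.path(dir, "random.h5"))
    save_recording_set(constant, paths["constant"])
    save_recording_set(random, paths["random"])
    out$paths <- paths
  }
  out
}
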