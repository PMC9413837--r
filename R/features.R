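#' Canonical EEG frequency bands
#'
#' Delta (1--3 Hz), Theta (4--7 Hz), Alpha (8--13 Hz), Beta (13--30 Hz)
#' and Gamma (30--45 Hz) — the five bands used for the differential-entropy
#' and band-power features.
#'
#' @return a named list of band definitions.
#' @export
eeg_bands <- function() {
  list(delta = band_definition("delta", 1, 3),
       theta = band_definition("theta", 4, 7),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' Define a frequency band
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return a `band_definition`.
#' @export
band_definition <- function(name, low, high) {
  assert_that(low > 0 && high > low, "need 0 < low < high (got %g, %g)",
              low, high)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]),
#' channel by channel, so the output is zero-phase and the same shape as the
#' input.
#'
#' @param segment numeric matrix `channels x T` (a vector is treated as a
#'   single channel).
#' @param fs sampling rate in Hz.
#' @param band a [band_definition()]; both edges must lie below the Nyquist
#'   frequency `fs/2`.
#' @param order filter order (default 4).
#' @return matrix of the same shape.
#' @export
bandpass_filter <- function(segment, fs, band, order = 4) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  assert_that(band$high < fs / 2,
              "band '%s' (%g-%g Hz) exceeds the Nyquist frequency %g Hz",
              band$name, band$low, band$high, fs / 2)
  bf <- signal::butter(order, c(band$low, band$high) / (fs / 2),
                       type = "pass")
  out <- segment
  for (m in seq_len(nrow(segment)))
    out[m, ] <- signal::filtfilt(bf, segment[m, ])
  out
}

#' Differential entropy per channel and band
#'
#' For a band-passed EEG segment modelled as Gaussian, the differential
#' entropy has the closed form `DE = 1/2 * log(2*pi*e*sigma^2)` where
#' `sigma^2` is the variance of the band-passed signal. With `bands = NULL`
#' the segment is used unfiltered (broadband DE).
#'
#' @param segment numeric matrix `channels x T`, `T >= fs` (at least 1 s).
#' @param fs sampling rate in Hz.
#' @param bands list of [band_definition()]s (default: the five canonical
#'   bands), or `NULL` for a single broadband value.
#' @param on_zero_variance `"error"` (default) or `"clamp"`; a clamped value
#'   replaces `sigma^2` with `.Machine$double.xmin`.
#' @return matrix `channels x n_bands`.
#' @export
differential_entropy <- function(segment, fs, bands = eeg_bands(),
                                 on_zero_variance = c("error", "clamp")) {
  on_zero_variance <- match.arg(on_zero_variance)
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  assert_that(ncol(segment) >= fs,
              "segment (%d samples) shorter than 1 s (fs = %d)",
              ncol(segment), as.integer(fs))
  if (is.null(bands)) bands <- list(band_definition("broadband", 1e-6, fs))
  out <- matrix(NA_real_, nrow(segment), length(bands),
                dimnames = list(NULL, vapply(bands, `[[`, "", "name")))
  for (b in seq_along(bands)) {
    band <- bands[[b]]
    x <- if (band$high >= fs / 2) segment else
      bandpass_filter(segment, fs, band)
    v <- apply(x, 1, stats::var)
    if (any(v <= 0)) {
      if (on_zero_variance == "error")
        stop2("zero-variance segment: differential entropy is -Inf")
      v[v <= 0] <- .Machine$double.xmin
    }
    out[, b] <- 0.5 * log(2 * pi * exp(1) * v)
  }
  out
}

#' Band power per channel from a single-window periodogram
#'
#' Computes a one-sided periodogram of each channel (scaled so that the sum
#' over all frequency bins equals the signal's mean square, i.e. Parseval's
#' identity holds) and integrates it over each band, giving the power the
#' signal carries inside the band. Band powers over disjoint bands therefore
#' sum to at most the total signal power, and for white noise they are
#' proportional to bandwidth.
#'
#' @inheritParams differential_entropy
#' @return matrix `channels x n_bands` of non-negative band powers.
#' @export
power_spectral_density <- function(segment, fs, bands = eeg_bands()) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  T <- ncol(segment)
  assert_that(T >= fs, "segment (%d samples) shorter than 1 s (fs = %d)",
              T, as.integer(fs))
  freqs <- (seq_len(T) - 1) * fs / T
  # one-sided: keep bins up to Nyquist, double the interior ones
  keep <- freqs <= fs / 2
  out <- matrix(NA_real_, nrow(segment), length(bands),
                dimnames = list(NULL, vapply(bands, `[[`, "", "name")))
  for (m in seq_len(nrow(segment))) {
    spec <- Mod(stats::fft(segment[m, ]))^2 / T^2   # power per bin
    one <- spec[keep]
    f1 <- freqs[keep]
    dbl <- f1 > 0 & f1 < fs / 2
    one[dbl] <- 2 * one[dbl]
    for (b in seq_along(bands)) {
      band <- bands[[b]]
      out[m, b] <- sum(one[f1 >= band$low & f1 <= band$high])
    }
  }
  out
}

#' Extract a feature set from every segment of a segment set
#'
#' @param seg a `segment_set`.
#' @param kind `"de"` or `"psd"`.
#' @param bands band list (default: five canonical bands).
#' @return a `feature_set` with `values` (`n_segments x channels x n_bands`),
#'   `kind` and `band_list`.
#' @export
extract_features <- function(seg, kind = c("de", "psd"),
                             bands = eeg_bands()) {
  kind <- match.arg(kind)
  n <- dim(seg$segments)[1]
  nc <- dim(seg$segments)[2]
  vals <- array(0, dim = c(n, nc, length(bands)))
  fun <- if (kind == "de") {
    function(x) differential_entropy(x, seg$fs, bands,
                                     on_zero_variance = "clamp")
  } else {
    function(x) power_spectral_density(x, seg$fs, bands)
  }
  for (i in seq_len(n)) vals[i, , ] <- fun(seg$segments[i, , , drop = TRUE])
  structure(list(values = vals, kind = kind, band_list = bands),
            class = "feature_set")
}

#' Assemble the model input tensor for a given input mode
#'
#' * `raw`: the segments unchanged (`C x T`);
#' * `de` / `psd`: the `C x n_bands` feature maps are the input
#'   (`T' = n_bands`);
#' * `raw+psd+de`: the raw `C x T` segment with the two `C x n_bands`
#'   feature maps appended along the time axis, each feature (channel, band)
#'   z-scored across segments first so the appended columns are on the raw
#'   signal's scale.
#'
#' @param seg a `segment_set`.
#' @param feats for `de`/`psd` modes, the matching `feature_set` (computed
#'   if omitted); for the combined mode, a list with elements `de` and
#'   `psd`.
#' @param mode input mode.
#' @return list with `x` (array `n x C' x T'`), `labels`, `trial_index`,
#'   `C`, `T` (the realised input height/width) and `mode`.
#' @export
assemble_model_input <- function(seg, feats = NULL,
                                 mode = c("raw", "de", "psd",
                                          "raw+psd+de")) {
  mode <- match.arg(mode)
  out <- function(x) list(x = x, labels = seg$labels,
                          trial_index = seg$trial_index,
                          C = dim(x)[2], T = dim(x)[3], mode = mode)
  if (mode == "raw") return(out(seg$segments))
  if (mode %in% c("de", "psd")) {
    if (is.null(feats)) feats <- extract_features(seg, mode)
    assert_that(feats$kind == mode, "feature_set kind '%s' != mode '%s'",
                feats$kind, mode)
    assert_that(dim(feats$values)[1] == dim(seg$segments)[1],
                "feature_set does not match segment_set")
    return(out(feats$values))
  }
  # combined: raw + z-scored psd + z-scored de along the time axis
  if (is.null(feats))
    feats <- list(de = extract_features(seg, "de"),
                  psd = extract_features(seg, "psd"))
  zscore <- function(v) {
    n <- dim(v)[1]
    m2 <- matrix(v, nrow = n)            # n x (C*bands)
    mu <- colMeans(m2)
    sd <- apply(m2, 2, stats::sd)
    sd[sd == 0] <- 1
    array(sweep(sweep(m2, 2, mu), 2, sd, "/"), dim = dim(v))
  }
  x <- array(0, dim = c(dim(seg$segments)[1], dim(seg$segments)[2],
                        seg$T + dim(feats$psd$values)[3] +
                          dim(feats$de$values)[3]))
  x[, , seq_len(seg$T)] <- seg$segments
  at <- seg$T
  for (f in list(zscore(feats$psd$values), zscore(feats$de$values))) {
    x[, , at + seq_len(dim(f)[3])] <- f
    at <- at + dim(f)[3]
  }
  out(x)
}
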