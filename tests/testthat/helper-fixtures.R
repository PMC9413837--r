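# Shared fixtures, built in code at test time.

# A tiny strongly-separable 2-class segment set: class 1 carries a 10 Hz
# oscillation three times larger than class 0, on top of white noise.
# T = 64 samples at fs = 64 keeps the model's pooling contract (64 = 2*32).
tiny_separable_segments <- function(n_per_class = 32, C = 2, fs = 64,
                                    seed = 404) {
  n <- 2 * n_per_class
  segs <- array(0, dim = c(n, C, fs))
  labels <- rep(0:1, each = n_per_class)
  tt <- (seq_len(fs) - 1) / fs
  e2ennet:::with_seed(seed, {
    for (i in seq_len(n)) {
      amp <- if (labels[i] == 1) 3 else 1
      for (ch in seq_len(C))
        segs[i, ch, ] <- amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 6)) +
          stats::rnorm(fs, sd = 0.5)
    }
  })
  # alternate classes so contiguous trial blocks stay balanced
  ord <- order(rep(seq_len(n_per_class), 2), labels)
  segment_set(segs[ord, , , drop = FALSE], labels[ord],
              trial_index = rep(seq_len(n %/% 8), each = 8)[seq_len(n)],
              fs = fs, n_classes = 2L)
}

# Small model configuration used across network tests.
tiny_model_config <- function(...) {
  model_config(C = 2, T = 32, n_classes = 2, F1 = 3, F2 = 4,
               lstm_units = c(5, 4), dropout_p = 0, temporal_kernel = 8,
               separable_kernel = 4, seed = 7, ...)
}

# Retrieve a nested element of a parameter/gradient list by path.
pluck_path <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

# Set a nested element by path (used by the finite-difference checks).
poke_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- poke_path(x[[path[[1]]]], path[-1], value)
  x
}
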