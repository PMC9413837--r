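#' Model architecture configuration
#'
#' Captures every architecture hyperparameter of the network: a temporal
#' convolution (`F1` kernels of length `temporal_kernel`), a depthwise
#' convolution of size `(C, 1)` with `depth_multiplier` kernels per feature
#' map (collapsing the electrode axis), a depthwise-separable convolution
#' (`separable_kernel`-wide depthwise stage plus a pointwise stage with `F2`
#' kernels), each followed by batch normalisation, with ELU activations,
#' average pooling (`pool1`, then `pool2`) and dropout, and finally a stack
#' of LSTM layers feeding a softmax classifier. The conv output is re-read
#' as a scalar sequence of length `F2 * T / (pool1*pool2)` for the first
#' LSTM, and each LSTM's final state is re-read as a scalar sequence for the
#' next.
#'
#' @param C number of EEG channels.
#' @param T samples per segment (must be divisible by `pool1 * pool2` for
#'   variants with a convolutional front-end).
#' @param n_classes number of emotion classes.
#' @param F1 temporal-convolution kernel count (default 8).
#' @param F2 pointwise kernel count of the separable stage (default 16).
#' @param depth_multiplier kernels per feature map in the depthwise stage
#'   (default 2).
#' @param lstm_units widths of the LSTM stack, 1 to 3 layers (default
#'   `c(64, 32)`).
#' @param dropout_p dropout probability (default 0.25, the usual
#'   within-subject setting for this model family).
#' @param pool1,pool2 average-pooling widths (defaults 4 and 8).
#' @param temporal_kernel temporal conv length (default 64).
#' @param separable_kernel separable conv length (default 16).
#' @param variant `"full"`, `"no_conv"` (LSTM stack on the raw segment,
#'   read as a `T`-step sequence of `C`-dimensional samples) or `"no_lstm"`
#'   (conv blocks, flatten, classifier).
#' @param peephole use the peephole gate equations (default `TRUE`);
#'   `FALSE` gives the standard LSTM.
#' @param bn_eps,bn_momentum batch-norm variance floor and running-moment
#'   momentum.
#' @param seed integer seed for weight initialisation.
#' @return a `model_config`.
#' @export
model_config <- function(C, T, n_classes, F1 = 8, F2 = 16,
                         depth_multiplier = 2, lstm_units = c(64, 32),
                         dropout_p = 0.25, pool1 = 4, pool2 = 8,
                         temporal_kernel = 64, separable_kernel = 16,
                         variant = c("full", "no_conv", "no_lstm"),
                         peephole = TRUE, bn_eps = 1e-3,
                         bn_momentum = 0.99, seed = 1L) {
  variant <- match.arg(variant)
  assert_that(F1 >= 1 && F2 >= 1, "F1 and F2 must be >= 1")
  assert_that(depth_multiplier >= 1, "depth_multiplier must be >= 1")
  assert_that(length(lstm_units) >= 1 && length(lstm_units) <= 3,
              "lstm_units must list 1 to 3 layer widths")
  assert_that(dropout_p >= 0 && dropout_p < 1, "dropout_p must be in [0,1)")
  if (variant != "no_conv")
    assert_that(T %% (pool1 * pool2) == 0,
      paste("T = %d is not divisible by pool1*pool2 = %d: the two average",
            "pooling stages must tile the time axis exactly; pick a window",
            "length or pool sizes that divide evenly"), T, pool1 * pool2)
  structure(list(C = as.integer(C), T = as.integer(T),
                 n_classes = as.integer(n_classes), F1 = as.integer(F1),
                 F2 = as.integer(F2),
                 depth_multiplier = as.integer(depth_multiplier),
                 lstm_units = as.integer(lstm_units),
                 dropout_p = dropout_p, pool1 = as.integer(pool1),
                 pool2 = as.integer(pool2),
                 temporal_kernel = as.integer(temporal_kernel),
                 separable_kernel = as.integer(separable_kernel),
                 variant = variant, peephole = isTRUE(peephole),
                 bn_eps = bn_eps, bn_momentum = bn_momentum,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build a network from a configuration
#'
#' Initialises all learned parameter arrays (Glorot-uniform weights, zero
#' biases except the LSTM forget-gate bias at 1, batch-norm scale 1 /
#' shift 0) from `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @return an `e2ennet_model` with elements `config`, `params` (learned
#'   arrays) and `running` (batch-norm running moments).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(cfg$seed, {
    glorot <- function(nr, nc, fan_in = nr, fan_out = nc)
      matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (fan_in + fan_out)),
             nr, nc)
    K2 <- cfg$F1 * cfg$depth_multiplier
    params <- list()
    running <- list()
    if (cfg$variant != "no_conv") {
      params$conv1 <- glorot(cfg$temporal_kernel, cfg$F1)
      params$bn1 <- list(gamma = rep(1, cfg$F1), beta = rep(0, cfg$F1))
      running$bn1 <- list(mean = rep(0, cfg$F1), var = rep(1, cfg$F1))
      dw <- array(stats::runif(cfg$C * cfg$F1 * cfg$depth_multiplier,
                               -1, 1) * sqrt(6 / (cfg$C + 1)),
                  dim = c(cfg$C, cfg$F1, cfg$depth_multiplier))
      params$dw <- dw
      params$bn2 <- list(gamma = rep(1, K2), beta = rep(0, K2))
      running$bn2 <- list(mean = rep(0, K2), var = rep(1, K2))
      params$sepd <- glorot(cfg$separable_kernel, K2,
                            fan_in = cfg$separable_kernel, fan_out = 1)
      params$sepp <- glorot(K2, cfg$F2)
      params$bn3 <- list(gamma = rep(1, cfg$F2), beta = rep(0, cfg$F2))
      running$bn3 <- list(mean = rep(0, cfg$F2), var = rep(1, cfg$F2))
    }
    if (cfg$variant != "no_lstm") {
      d_first <- if (cfg$variant == "no_conv") cfg$C else 1L
      params$lstm <- list()
      D <- d_first
      for (l in seq_along(cfg$lstm_units)) {
        H <- cfg$lstm_units[l]
        params$lstm[[l]] <- lstm_init(D, H, cfg$peephole)
        D <- 1L   # the next layer consumes the state as a scalar sequence
      }
      d_dense <- cfg$lstm_units[length(cfg$lstm_units)]
    } else {
      d_dense <- cfg$F2 * (cfg$T %/% (cfg$pool1 * cfg$pool2))
    }
    params$dense <- list(W = glorot(d_dense, cfg$n_classes),
                         b = rep(0, cfg$n_classes))
    structure(list(config = cfg, params = params, running = running),
              class = "e2ennet_model")
  })
}

#' @export
print.e2ennet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<e2ennet_model> variant %s: C=%d T=%d F1=%d F2=%d, LSTM [%s], %d classes\n  %d learned parameters\n",
    cfg$variant, cfg$C, cfg$T, cfg$F1, cfg$F2,
    paste(cfg$lstm_units, collapse = ", "), cfg$n_classes,
    count_parameters(x)))
  invisible(x)
}

#' Total number of learned parameters
#' @param model an `e2ennet_model`.
#' @return integer count of learned scalars.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

#' Cost ratio of a depthwise-separable vs. a standard convolution
#'
#' A standard convolution with an `Sk x Sk` kernel, `M` input and `N` output
#' channels over an `Sf x Sf` map costs `Sk^2 * M * N * Sf^2` multiplies;
#' splitting it into a depthwise stage (`Sk^2 * M * Sf^2`) plus a pointwise
#' stage (`M * N * Sf^2`) costs the fraction `1/N + 1/Sk^2` of that.
#'
#' @param Sk kernel side length (>= 1).
#' @param N number of output channels (>= 1).
#' @return the cost ratio `1/N + 1/Sk^2`.
#' @export
conv_cost_ratio <- function(Sk, N) {
  assert_that(Sk >= 1 && N >= 1, "Sk and N must be >= 1")
  1 / N + 1 / Sk^2
}

#' Expected intermediate activation shapes
#'
#' The layer-by-layer output shapes of the full architecture for a
#' configuration, in `(height, width, maps)` form (the batch axis omitted):
#' the contract every forward pass must honour.
#'
#' @param cfg a [model_config()] with `variant = "full"`.
#' @return named list of integer shape vectors.
#' @export
model_shapes <- function(cfg) {
  K2 <- cfg$F1 * cfg$depth_multiplier
  t4 <- cfg$T %/% cfg$pool1
  t32 <- t4 %/% cfg$pool2
  list(input = c(cfg$C, cfg$T),
       reshape = c(cfg$C, cfg$T, 1L),
       conv2d = c(cfg$C, cfg$T, cfg$F1),
       batchnorm1 = c(cfg$C, cfg$T, cfg$F1),
       depthwise = c(1L, cfg$T, K2),
       batchnorm2 = c(1L, cfg$T, K2),
       pool1 = c(1L, t4, K2),
       separable = c(1L, t4, cfg$F2),
       batchnorm3 = c(1L, t4, cfg$F2),
       pool2 = c(1L, t32, cfg$F2),
       sequence = c(cfg$F2 * t32, 1L),
       lstm1 = cfg$lstm_units[1],
       lstm2 = if (length(cfg$lstm_units) > 1) cfg$lstm_units[2] else NULL,
       dense = cfg$n_classes)
}
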