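# Vectorised layer primitives with explicit forward / backward passes.
#
# Conventions: the batch axis comes first everywhere; each forward returns
# list(out = ..., cache = ...) and the matching backward takes (d_out, cache)
# and returns list(dx = ..., d<param> = ...). All convolutions are stride-1,
# bias-free (each one is followed by batch normalisation).

# ---- 1-D temporal convolution (same padding) over row streams -------------

# x: R x T matrix of R independent signal streams; W: k x F kernel bank.
# Same padding follows the floor((k-1)/2) / ceil((k-1)/2) left/right split.
conv1d_same_forward <- function(x, W) {
  R <- nrow(x); T <- ncol(x); k <- nrow(W)
  pl <- (k - 1L) %/% 2L
  xp <- matrix(0, R, T + k - 1L)
  xp[, pl + seq_len(T)] <- x
  idx <- outer(seq_len(T), seq_len(k) - 1L, `+`)   # T x k positions into xp
  cols <- xp[, as.vector(idx), drop = FALSE]       # R x (T*k)
  dim(cols) <- c(R * T, k)
  out <- cols %*% W                                # (R*T) x F
  list(out = out, cache = list(cols = cols, R = R, T = T, k = k, W = W))
}

conv1d_same_backward <- function(d_out, cache) {
  R <- cache$R; T <- cache$T; k <- cache$k
  dW <- crossprod(cache$cols, d_out)
  dcols <- d_out %*% t(cache$W)                    # (R*T) x k
  dim(dcols) <- c(R, T, k)
  dxp <- matrix(0, R, T + k - 1L)
  for (j in seq_len(k))
    dxp[, j:(j + T - 1L)] <- dxp[, j:(j + T - 1L)] + dcols[, , j]
  pl <- (k - 1L) %/% 2L
  list(dx = dxp[, pl + seq_len(T), drop = FALSE], dW = dW)
}

# ---- batch normalisation ---------------------------------------------------

# x: n x F matrix (features in columns). Batch moments use the biased
# variance, as deep-learning frameworks do.
bn_forward <- function(x, gamma, beta, running, training,
                       eps = 1e-3, momentum = 0.99) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v[v < 0] <- 0
    new_running <- list(mean = momentum * running$mean + (1 - momentum) * mu,
                        var = momentum * running$var + (1 - momentum) * v)
  } else {
    mu <- running$mean
    v <- running$var
    new_running <- running
  }
  ivar <- 1 / sqrt(v + eps)
  ap <- bn_apply_cpp(x, mu, ivar, gamma, beta)
  list(out = ap$out, running = new_running,
       cache = list(xhat = ap$xhat, ivar = ivar, gamma = gamma,
                    training = training))
}

bn_backward <- function(d_out, cache) {
  if (cache$training) {
    r <- bn_backward_train_cpp(d_out, cache$xhat, cache$ivar, cache$gamma)
    return(list(dx = r$dx, dgamma = as.numeric(r$dgamma),
                dbeta = as.numeric(r$dbeta)))
  }
  list(dx = sweep(sweep(d_out, 2, cache$gamma, "*"), 2, cache$ivar, "*"),
       dgamma = colSums(d_out * cache$xhat), dbeta = colSums(d_out))
}

#' Batch normalisation of a feature matrix
#'
#' Normalises each column to zero mean and unit variance using either the
#' batch's own moments (training mode) or supplied running moments
#' (inference mode), then applies the learned scale and shift. A small
#' epsilon keeps the variance denominator away from zero.
#'
#' @param x numeric matrix, observations in rows, features in columns.
#' @param gamma,beta learned per-feature scale and shift (default 1 / 0).
#' @param moments optional list with `mean` and `var` per feature; when
#'   supplied the function normalises by these running moments (inference),
#'   otherwise by the batch moments (training).
#' @param eps variance floor.
#' @return matrix of the same shape.
#' @export
batch_normalize <- function(x, gamma = rep(1, ncol(x)),
                            beta = rep(0, ncol(x)), moments = NULL,
                            eps = 1e-3) {
  training <- is.null(moments)
  running <- if (training) list(mean = rep(0, ncol(x)), var = rep(1, ncol(x)))
             else moments
  bn_forward(x, gamma, beta, running, training = training, eps = eps)$out
}

# ---- activations, pooling, dropout ----------------------------------------

elu_forward <- function(x) {
  out <- x
  neg <- x < 0
  out[neg] <- exp(x[neg]) - 1
  list(out = out, cache = out)
}

elu_backward <- function(d_out, cache) {
  d <- d_out
  neg <- cache < 0
  d[neg] <- d[neg] * (cache[neg] + 1)
  d
}

# x: (B, T, K) array; average-pool along the middle (time) axis with floor
# semantics: trailing positions that do not fill a window are dropped.
avgpool_forward <- function(x, p) {
  d <- dim(x)
  Tn <- d[2] %/% p
  acc <- x[, seq(1, by = p, length.out = Tn), , drop = FALSE]
  if (p > 1) for (o in seq_len(p - 1))
    acc <- acc + x[, seq(1 + o, by = p, length.out = Tn), , drop = FALSE]
  list(out = acc / p, cache = list(dim = d, p = p, Tn = Tn))
}

avgpool_backward <- function(d_out, cache) {
  dx <- array(0, dim = cache$dim)
  g <- d_out / cache$p
  for (o in seq_len(cache$p) - 1L)
    dx[, seq(1 + o, by = cache$p, length.out = cache$Tn), ] <- g
  dx
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0)
    return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(d_out, cache) {
  if (is.null(cache)) d_out else d_out * cache
}

# ---- dense + softmax + loss ------------------------------------------------

dense_forward <- function(h, W, b) {
  list(out = sweep(h %*% W, 2, b, "+"), cache = h)
}

dense_backward <- function(d_out, cache, W) {
  list(dx = d_out %*% t(W), dW = crossprod(cache, d_out),
       db = colSums(d_out))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean cross-entropy of predicted class probabilities
#'
#' `-mean(log P[true class])` over the batch, with probabilities clamped at
#' `1e-12` so a confidently wrong prediction yields a large finite loss.
#'
#' @param probs numeric matrix `B x N` of class probabilities (rows sum
#'   to 1).
#' @param labels integer vector of 0-based true classes, length `B`.
#' @return scalar loss (>= 0).
#' @export
cross_entropy_loss <- function(probs, labels) {
  assert_that(nrow(probs) == length(labels),
              "probs rows (%d) != labels length (%d)",
              nrow(probs), length(labels))
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# Combined softmax + cross-entropy gradient wrt logits.
softmax_ce_backward <- function(probs, labels) {
  B <- nrow(probs)
  d <- probs
  idx <- cbind(seq_len(B), as.integer(labels) + 1L)
  d[idx] <- d[idx] - 1
  d / B
}
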