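# End-to-end forward and backward passes. net_forward() records every
# intermediate needed by net_backward(); the exported forward() returns the
# class probabilities only.

#' Run the network on a batch of segments
#'
#' @param model an `e2ennet_model` from [build_model()].
#' @param batch numeric array `B x C x T` (a single `C x T` matrix is
#'   treated as a batch of one).
#' @param training logical; in training mode batch normalisation uses the
#'   batch's own moments and dropout is active (dropout draws from R's
#'   RNG). In inference mode (default) the stored running moments are used
#'   and the pass is deterministic.
#' @return matrix `B x n_classes` of class probabilities (rows sum to 1).
#' @export
forward <- function(model, batch, training = FALSE) {
  net_forward(model, batch, training = training)$probs
}

net_forward <- function(model, batch, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (length(dim(batch)) == 2)
    batch <- array(batch, dim = c(1L, dim(batch)))
  d <- dim(batch)
  assert_that(d[2] == cfg$C && d[3] == cfg$T,
              "batch is %d x %d but the model expects C=%d, T=%d",
              d[2], d[3], cfg$C, cfg$T)
  B <- d[1]
  cache <- list(B = B, training = training, shapes = list())
  rshape <- function(name, s) cache$shapes[[name]] <<- s
  rshape("input", c(cfg$C, cfg$T))

  h <- NULL
  if (cfg$variant != "no_conv") {
    K2 <- cfg$F1 * cfg$depth_multiplier
    # block 1: temporal convolution over each (trial, electrode) stream
    x2 <- batch; dim(x2) <- c(B * cfg$C, cfg$T)
    conv1_out <- conv1_forward_cpp(x2, p$conv1)     # (B*C*T) x F1
    cache$conv1_in <- x2
    rshape("conv2d", c(cfg$C, cfg$T, cfg$F1))
    bn1 <- bn_forward(conv1_out, p$bn1$gamma, p$bn1$beta,
                      model$running$bn1, training, cfg$bn_eps,
                      cfg$bn_momentum)
    cache$bn1 <- bn1$cache
    if (training) model$running$bn1 <- bn1$running
    rshape("batchnorm1", c(cfg$C, cfg$T, cfg$F1))

    # block 2: depthwise (C,1) conv collapses the electrode axis
    dwo <- depthwise_forward_cpp(bn1$out, p$dw, B, cfg$C, cfg$T)
    cache$dw_in <- bn1$out
    rshape("depthwise", c(1L, cfg$T, K2))
    bn2 <- bn_forward(dwo, p$bn2$gamma, p$bn2$beta, model$running$bn2,
                      training, cfg$bn_eps, cfg$bn_momentum)
    cache$bn2 <- bn2$cache
    if (training) model$running$bn2 <- bn2$running
    rshape("batchnorm2", c(1L, cfg$T, K2))
    e1 <- elu_forward(bn2$out)
    cache$elu1 <- e1$cache
    a2 <- array(e1$out, dim = c(B, cfg$T, K2))
    p1 <- avgpool_forward(a2, cfg$pool1)            # (B, T/4, K2)
    cache$pool1 <- p1$cache
    t4 <- dim(p1$out)[2]
    rshape("pool1", c(1L, t4, K2))
    dr1 <- dropout_forward(p1$out, cfg$dropout_p, training)
    cache$drop1 <- dr1$cache

    # block 3: separable conv = per-map temporal conv + pointwise mix
    x3 <- dr1$out                                   # (B, T4, K2)
    sd_out <- sepconv_forward_cpp(x3, p$sepd)
    cache$sepd_in <- x3
    sdm <- sd_out; dim(sdm) <- c(B * t4, K2)
    pw <- sdm %*% p$sepp                            # (B*T4) x F2
    cache$sep_in <- sdm
    rshape("separable", c(1L, t4, cfg$F2))
    bn3 <- bn_forward(pw, p$bn3$gamma, p$bn3$beta, model$running$bn3,
                      training, cfg$bn_eps, cfg$bn_momentum)
    cache$bn3 <- bn3$cache
    if (training) model$running$bn3 <- bn3$running
    rshape("batchnorm3", c(1L, t4, cfg$F2))
    e2 <- elu_forward(bn3$out)
    cache$elu2 <- e2$cache
    a3 <- array(e2$out, dim = c(B, t4, cfg$F2))
    p2 <- avgpool_forward(a3, cfg$pool2)            # (B, T32, F2)
    cache$pool2 <- p2$cache
    t32 <- dim(p2$out)[2]
    rshape("pool2", c(1L, t32, cfg$F2))
    dr2 <- dropout_forward(p2$out, cfg$dropout_p, training)
    cache$drop2 <- dr2$cache
    cache$t4 <- t4; cache$t32 <- t32

    # flatten time-major with maps fastest: s = (t-1)*F2 + k
    flat <- aperm(dr2$out, c(1, 3, 2))
    dim(flat) <- c(B, cfg$F2 * t32)
    rshape("sequence", c(cfg$F2 * t32, 1L))
    h <- flat
  }

  if (cfg$variant == "no_lstm") {
    dn <- dense_forward(h, p$dense$W, p$dense$b)
  } else {
    if (cfg$variant == "no_conv") {
      x_seq <- aperm(batch, c(1, 3, 2))             # (B, T, C)
      rshape("sequence", c(cfg$T, cfg$C))
    } else {
      x_seq <- array(h, dim = c(B, ncol(h), 1L))
    }
    cache$lstm <- vector("list", length(p$lstm))
    for (l in seq_along(p$lstm)) {
      lf <- lstm_forward(x_seq, p$lstm[[l]])
      cache$lstm[[l]] <- lf$cache
      rshape(paste0("lstm", l), ncol(lf$h))
      h <- lf$h
      if (l < length(p$lstm))
        x_seq <- array(h, dim = c(B, ncol(h), 1L))
    }
    dn <- dense_forward(h, p$dense$W, p$dense$b)
  }
  cache$dense <- dn$cache
  rshape("dense", cfg$n_classes)
  logits <- dn$out
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, cache = cache, model = model)
}

net_backward <- function(model, cache, d_logits) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  g <- list()

  dd <- dense_backward(d_logits, cache$dense, p$dense$W)
  g$dense <- list(W = dd$dW, b = dd$db)
  dh <- dd$dx

  if (cfg$variant != "no_lstm") {
    g$lstm <- vector("list", length(p$lstm))
    for (l in rev(seq_along(p$lstm))) {
      lb <- lstm_backward(dh, cache$lstm[[l]])
      g$lstm[[l]] <- lb$grads
      if (l > 1) {
        dh <- lb$dx_seq
        dim(dh) <- c(B, dim(lb$dx_seq)[2])          # scalar sequence -> state
      } else {
        d_seq_in <- lb$dx_seq
      }
    }
    if (cfg$variant == "no_conv") {
      return(g)   # input gradients not needed
    }
    dflat <- d_seq_in
    dim(dflat) <- c(B, cfg$F2 * cache$t32)
  } else {
    dflat <- dh
  }

  # undo the maps-fastest flatten
  t32 <- cache$t32; t4 <- cache$t4
  K2 <- cfg$F1 * cfg$depth_multiplier
  dp2 <- array(dflat, dim = c(B, cfg$F2, t32))
  dp2 <- aperm(dp2, c(1, 3, 2))                     # (B, T32, F2)
  dp2 <- dropout_backward(dp2, cache$drop2)
  da3 <- avgpool_backward(dp2, cache$pool2)         # (B, T4, F2)
  de2 <- da3; dim(de2) <- c(B * t4, cfg$F2)
  de2 <- elu_backward(de2, cache$elu2)
  b3 <- bn_backward(de2, cache$bn3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  dpw <- b3$dx                                      # (B*T4) x F2
  g$sepp <- crossprod(cache$sep_in, dpw)
  dsdm <- dpw %*% t(p$sepp)                         # (B*T4) x K2
  dsd <- array(dsdm, dim = c(B, t4, K2))
  sb <- sepconv_backward_cpp(dsd, cache$sepd_in, p$sepd)
  g$sepd <- sb$dW
  dx3 <- sb$dx
  dx3 <- dropout_backward(dx3, cache$drop1)
  da2 <- avgpool_backward(dx3, cache$pool1)         # (B, T, K2)
  de1 <- da2; dim(de1) <- c(B * cfg$T, K2)
  de1 <- elu_backward(de1, cache$elu1)
  b2 <- bn_backward(de1, cache$bn2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  ddwo <- b2$dx                                     # (B*T) x K2
  dwb <- depthwise_backward_cpp(ddwo, cache$dw_in, p$dw, B, cfg$C, cfg$T)
  g$dw <- dwb$dW
  b1 <- bn_backward(dwb$da, cache$bn1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  cv <- conv1_backward_cpp(b1$dx, cache$conv1_in, p$conv1, FALSE)
  g$conv1 <- cv$dW
  g
}

# Loss and gradients for one labelled batch (the training step's core).
net_loss_grads <- function(model, batch, labels, training = TRUE) {
  fw <- net_forward(model, batch, training = training)
  loss <- cross_entropy_loss(fw$probs, labels)
  d_logits <- softmax_ce_backward(fw$probs, labels)
  grads <- net_backward(fw$model, fw$cache, d_logits)
  list(loss = loss, grads = grads, probs = fw$probs, model = fw$model)
}

#' Predict class probabilities for a set of segments
#'
#' Runs the model in inference mode (running batch-norm moments, no
#' dropout) over mini-batches, so the result for a segment does not depend
#' on which other segments share its batch.
#'
#' @param model a trained `e2ennet_model`.
#' @param x array `n x C x T` of segments, or a `segment_set`.
#' @param batch_size evaluation batch size.
#' @return matrix `n x n_classes` of probabilities.
#' @export
predict_proba <- function(model, x, batch_size = 256) {
  if (inherits(x, "segment_set")) x <- x$segments
  n <- dim(x)[1]
  out <- matrix(0, n, model$config$n_classes)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    out[idx, ] <- forward(model, x[idx, , , drop = FALSE],
                          training = FALSE)
    at <- at + batch_size
  }
  out
}
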