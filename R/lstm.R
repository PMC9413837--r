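# Peephole LSTM: batched sequence forward pass and backpropagation through
# time. Gate layout in the packed weight matrices is [input, forget, cell,
# output] (i, g, c, o). The peephole terms are diagonal, i.e. one weight per
# unit, entering the input and forget gates from c_{t-1} and the output gate
# from c_t:
#
#   i_t = sigmoid(x_t Wxi + h_{t-1} Whi + p_i * c_{t-1} + b_i)
#   g_t = sigmoid(x_t Wxg + h_{t-1} Whg + p_g * c_{t-1} + b_g)   (forget)
#   c_t = g_t * c_{t-1} + i_t * tanh(x_t Wxc + h_{t-1} Whc + b_c)
#   o_t = sigmoid(x_t Wxo + h_{t-1} Who + p_o * c_t + b_o)
#   h_t = o_t * tanh(c_t)
#
# Setting the peephole vectors to zero (peephole = FALSE in the model
# config) recovers the standard Keras-style LSTM.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Initialise one LSTM layer's packed weights: Wx (D x 4H) Glorot-uniform,
# Wh (H x 4H) orthogonal per gate (the usual recurrent-kernel choice),
# b (4H, forget-gate slice initialised to 1), peepholes p_i/p_g/p_o (H).
lstm_init <- function(D, H, peephole) {
  glorot <- function(nr, nc)
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  ortho <- function(n) {
    qr_ <- qr(matrix(stats::rnorm(n * n), n))
    q <- qr.Q(qr_)
    q * sign(diag(qr.R(qr_)))[col(q)]
  }
  b <- rep(0, 4 * H)
  b[H + seq_len(H)] <- 1          # forget-gate bias
  Wh <- do.call(cbind, lapply(1:4, function(i) ortho(H)))
  w <- list(Wx = glorot(D, 4 * H), Wh = Wh, b = b)
  if (peephole) {
    w$p_i <- rep(0, H); w$p_g <- rep(0, H); w$p_o <- rep(0, H)
  }
  w
}

#' One step of the peephole LSTM recurrence
#'
#' Advances the LSTM state by a single time step using the gate equations
#' above, with weights given under their per-gate names. Peephole weight
#' vectors (`W_ci`, `W_cg`, `W_co`) may be omitted or `NULL`, which drops
#' the peephole terms.
#'
#' @param x_t input at this step: a vector of length `D` or a `B x D`
#'   matrix.
#' @param state list with `h` and `c`, each a vector of length `H` or a
#'   `B x H` matrix (use zeros for the initial state).
#' @param weights named list: matrices `W_xi, W_hi, W_xg, W_hg, W_xc, W_hc,
#'   W_xo, W_ho` (`D x H` / `H x H`), bias vectors `b_i, b_g, b_c, b_o`
#'   (length `H`) and optional peephole vectors `W_ci, W_cg, W_co`.
#' @return list with the new `h` and `c` (matching the input's shape).
#' @export
lstm_step <- function(x_t, state, weights) {
  vec_in <- is.null(dim(x_t))
  x <- if (vec_in) matrix(x_t, nrow = 1) else x_t
  h <- if (is.null(dim(state$h))) matrix(state$h, nrow = 1) else state$h
  c_prev <- if (is.null(dim(state$c))) matrix(state$c, nrow = 1) else state$c
  B <- nrow(x)
  peep <- function(p, cc) if (is.null(p)) 0 else
    cc * matrix(p, B, length(p), byrow = TRUE)

  i <- sigmoid(x %*% weights$W_xi + h %*% weights$W_hi +
                 peep(weights$W_ci, c_prev) +
                 matrix(weights$b_i, B, length(weights$b_i), byrow = TRUE))
  g <- sigmoid(x %*% weights$W_xg + h %*% weights$W_hg +
                 peep(weights$W_cg, c_prev) +
                 matrix(weights$b_g, B, length(weights$b_g), byrow = TRUE))
  cbar <- tanh(x %*% weights$W_xc + h %*% weights$W_hc +
                 matrix(weights$b_c, B, length(weights$b_c), byrow = TRUE))
  c_new <- g * c_prev + i * cbar
  o <- sigmoid(x %*% weights$W_xo + h %*% weights$W_ho +
                 peep(weights$W_co, c_new) +
                 matrix(weights$b_o, B, length(weights$b_o), byrow = TRUE))
  h_new <- o * tanh(c_new)
  if (vec_in) list(h = drop(h_new), c = drop(c_new))
  else list(h = h_new, c = c_new)
}

# Batched forward over a whole sequence with packed weights. The input
# projection x W_x + b is one BLAS call; the sequential recurrence runs in
# compiled code. x_seq: (B, S, D) array. Returns final h and the BPTT cache.
lstm_forward <- function(x_seq, w) {
  d <- dim(x_seq)
  B <- d[1]; S <- d[2]; D <- d[3]
  H <- ncol(w$Wh) / 4L
  xf <- x_seq
  dim(xf) <- c(B * S, D)
  XW <- xf %*% w$Wx          # bias is applied inside the kernel
  peep <- !is.null(w$p_i)
  z <- numeric(if (peep) H else 1)
  fw <- lstm_seq_forward_cpp(XW, w$Wh, w$b,
                             if (peep) w$p_i else z,
                             if (peep) w$p_g else z,
                             if (peep) w$p_o else z,
                             peep, B, S, H)
  list(h = fw$h,
       cache = list(xf = xf, B = B, S = S, D = D, H = H, w = w,
                    I = fw$I, G = fw$G, CB = fw$CB, O = fw$O,
                    Cs = fw$Cs, Hs = fw$Hs, peep = peep))
}

# BPTT given the gradient wrt the final hidden state (B x H).
lstm_backward <- function(d_h_final, cache) {
  w <- cache$w; peep <- cache$peep; H <- cache$H
  z <- numeric(if (peep) H else 1)
  bw <- lstm_seq_backward_cpp(d_h_final, w$Wh,
                              if (peep) w$p_i else z,
                              if (peep) w$p_g else z,
                              if (peep) w$p_o else z,
                              peep, cache$I, cache$G, cache$CB, cache$O,
                              cache$Cs, cache$Hs)
  dXW <- bw$dXW
  grads <- list(Wx = crossprod(cache$xf, dXW), Wh = bw$dWh,
                b = colSums(dXW))
  if (peep) {
    grads$p_i <- as.numeric(bw$dpi)
    grads$p_g <- as.numeric(bw$dpg)
    grads$p_o <- as.numeric(bw$dpo)
  }
  dxf <- dXW %*% t(w$Wx)
  list(dx_seq = array(dxf, dim = c(cache$B, cache$S, cache$D)),
       grads = grads)
}

# Expose packed weights under the per-gate naming used by lstm_step()
# (for tests and inspection).
lstm_unpack <- function(w) {
  H <- ncol(w$Wh) / 4
  ii <- seq_len(H)
  list(W_xi = w$Wx[, ii, drop = FALSE],
       W_xg = w$Wx[, H + ii, drop = FALSE],
       W_xc = w$Wx[, 2 * H + ii, drop = FALSE],
       W_xo = w$Wx[, 3 * H + ii, drop = FALSE],
       W_hi = w$Wh[, ii, drop = FALSE],
       W_hg = w$Wh[, H + ii, drop = FALSE],
       W_hc = w$Wh[, 2 * H + ii, drop = FALSE],
       W_ho = w$Wh[, 3 * H + ii, drop = FALSE],
       b_i = w$b[ii], b_g = w$b[H + ii], b_c = w$b[2 * H + ii],
       b_o = w$b[3 * H + ii],
       W_ci = w$p_i, W_cg = w$p_g, W_co = w$p_o)
}
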