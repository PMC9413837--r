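// Compiled kernels for the two interpreter-bound inner loops: the LSTM
// recurrence (forward + backpropagation through time) and the per-map
// temporal convolution of the separable block. The input projection
// x_t * Wx + b is precomputed in R (one large BLAS call); these kernels
// handle the sequential part. Gate column layout is [i, g, c, o].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// XW: (B*S) x 4H input projections (bias already added), Wh: H x 4H,
// p_i/p_g/p_o: peephole vectors (ignored unless peephole). Returns the
// final hidden state and the cached gate activations for BPTT. The gate
// non-linearities run in one fused pass per step over pre-allocated
// buffers; the only per-step BLAS call is the recurrent projection.
// [[Rcpp::export]]
Rcpp::List lstm_seq_forward_cpp(const arma::mat& XW, const arma::mat& Wh,
                                const arma::vec& b, const arma::vec& p_i,
                                const arma::vec& p_g, const arma::vec& p_o,
                                bool peephole, int B, int S, int H) {
  cube I(B, H, S), G(B, H, S), CB(B, H, S), O(B, H, S), Cs(B, H, S),
      Hs(B, H, S);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat A(B, 4 * H);
  const size_t BH = (size_t)B * H;
  const double* pi = p_i.memptr();
  const double* pg = p_g.memptr();
  const double* po = p_o.memptr();
  for (int t = 0; t < S; ++t) {
    A = XW.rows(t * B, t * B + B - 1);
    A += h * Wh;
    const double* ai = A.memptr();
    const double* ag = ai + BH;
    const double* ac = ai + 2 * BH;
    const double* ao = ai + 3 * BH;
    double* cp = c.memptr();
    double* hp = h.memptr();
    double* Ip = I.slice_memptr(t);
    double* Gp = G.slice_memptr(t);
    double* CBp = CB.slice_memptr(t);
    double* Op = O.slice_memptr(t);
    double* Cp = Cs.slice_memptr(t);
    double* Hp = Hs.slice_memptr(t);
    const double* bp = b.memptr();
    for (size_t k = 0; k < BH; ++k) {
      const size_t col = k / B;
      double zi = ai[k] + bp[col], zg = ag[k] + bp[H + col];
      if (peephole) { zi += cp[k] * pi[col]; zg += cp[k] * pg[col]; }
      const double it = 1.0 / (1.0 + std::exp(-zi));
      const double gt = 1.0 / (1.0 + std::exp(-zg));
      const double cb = std::tanh(ac[k] + bp[2 * H + col]);
      const double cn = gt * cp[k] + it * cb;
      double zo = ao[k] + bp[3 * H + col];
      if (peephole) zo += cn * po[col];
      const double ot = 1.0 / (1.0 + std::exp(-zo));
      const double hn = ot * std::tanh(cn);
      Ip[k] = it; Gp[k] = gt; CBp[k] = cb; Op[k] = ot; Cp[k] = cn;
      Hp[k] = hn;
      cp[k] = cn; hp[k] = hn;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = h, Rcpp::Named("I") = I, Rcpp::Named("G") = G,
      Rcpp::Named("CB") = CB, Rcpp::Named("O") = O, Rcpp::Named("Cs") = Cs,
      Rcpp::Named("Hs") = Hs);
}

// BPTT given the gradient of the loss w.r.t. the final hidden state.
// Returns dXW (gradients of the packed pre-activations), dWh and the
// peephole gradients. Mirrors the fused-forward layout.
// [[Rcpp::export]]
Rcpp::List lstm_seq_backward_cpp(const arma::mat& d_h_final,
                                 const arma::mat& Wh,
                                 const arma::vec& p_i, const arma::vec& p_g,
                                 const arma::vec& p_o, bool peephole,
                                 const arma::cube& I, const arma::cube& G,
                                 const arma::cube& CB, const arma::cube& O,
                                 const arma::cube& Cs,
                                 const arma::cube& Hs) {
  const int B = I.n_rows, H = I.n_cols, S = I.n_slices;
  const size_t BH = (size_t)B * H;
  mat dXW(B * S, 4 * H);
  mat dWh(H, 4 * H, fill::zeros);
  vec dpi(H, fill::zeros), dpg(H, fill::zeros), dpo(H, fill::zeros);
  const double* pi = p_i.memptr();
  const double* pg = p_g.memptr();
  const double* po = p_o.memptr();
  const mat WhT = Wh.t();
  const mat zero(B, H, fill::zeros);
  mat dh = d_h_final;
  mat dc(B, H, fill::zeros);
  mat dA(B, 4 * H);
  for (int t = S - 1; t >= 0; --t) {
    const double* Ip = I.slice_memptr(t);
    const double* Gp = G.slice_memptr(t);
    const double* CBp = CB.slice_memptr(t);
    const double* Op = O.slice_memptr(t);
    const double* Cp = Cs.slice_memptr(t);
    const double* Cprev = (t > 0) ? Cs.slice_memptr(t - 1) : zero.memptr();
    double* dhp = dh.memptr();
    double* dcp = dc.memptr();
    double* dai = dA.memptr();
    double* dag = dai + BH;
    double* dac = dai + 2 * BH;
    double* dao = dai + 3 * BH;
    for (size_t k = 0; k < BH; ++k) {
      const size_t col = k / B;
      const double tc = std::tanh(Cp[k]);
      const double d_o = dhp[k] * tc;
      const double da_o = d_o * Op[k] * (1.0 - Op[k]);
      double dck = dcp[k] + dhp[k] * Op[k] * (1.0 - tc * tc);
      if (peephole) {
        dck += da_o * po[col];
        dpo(col) += da_o * Cp[k];
      }
      const double da_i = (dck * CBp[k]) * Ip[k] * (1.0 - Ip[k]);
      const double da_g = (dck * Cprev[k]) * Gp[k] * (1.0 - Gp[k]);
      const double da_c = (dck * Ip[k]) * (1.0 - CBp[k] * CBp[k]);
      double dc_prev = dck * Gp[k];
      if (peephole) {
        dc_prev += da_i * pi[col] + da_g * pg[col];
        dpi(col) += da_i * Cprev[k];
        dpg(col) += da_g * Cprev[k];
      }
      dai[k] = da_i; dag[k] = da_g; dac[k] = da_c; dao[k] = da_o;
      dcp[k] = dc_prev;
    }
    dXW.rows(t * B, t * B + B - 1) = dA;
    if (t > 0) {
      dWh += Hs.slice(t - 1).t() * dA;
      dh = dA * WhT;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("dXW") = dXW, Rcpp::Named("dWh") = dWh,
      Rcpp::Named("dpi") = dpi, Rcpp::Named("dpg") = dpg,
      Rcpp::Named("dpo") = dpo);
}

// Per-map temporal convolution, stride 1, same padding: one kernel per
// feature map. x: (B, T, K) cube, W: ks x K, pad_left = floor((ks-1)/2).
// out[b,t,k] = sum_j x[b, t+j-pl, k] * W(j,k)   (zero outside [0,T)).
// [[Rcpp::export]]
arma::cube sepconv_forward_cpp(const arma::cube& x, const arma::mat& W) {
  const int B = x.n_rows, T = x.n_cols, K = x.n_slices, ks = W.n_rows;
  const int pl = (ks - 1) / 2;
  cube out(B, T, K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < ks; ++j) {
      const double w = W(j, k);
      if (w == 0.0) continue;
      const int lo = std::max(0, pl - j);
      const int hi = std::min(T - 1, T - 1 + pl - j);
      if (lo > hi) continue;
      out.slice(k).cols(lo, hi) += w * x.slice(k).cols(lo - pl + j,
                                                       hi - pl + j);
    }
  }
  return out;
}

// Backward pass of sepconv_forward_cpp: gradients w.r.t. x and W.
// [[Rcpp::export]]
Rcpp::List sepconv_backward_cpp(const arma::cube& d_out,
                                const arma::cube& x, const arma::mat& W) {
  const int B = x.n_rows, T = x.n_cols, K = x.n_slices, ks = W.n_rows;
  const int pl = (ks - 1) / 2;
  cube dx(B, T, K, fill::zeros);
  mat dW(ks, K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < ks; ++j) {
      const int lo = std::max(0, pl - j);
      const int hi = std::min(T - 1, T - 1 + pl - j);
      if (lo > hi) continue;
      dW(j, k) = accu(d_out.slice(k).cols(lo, hi) %
                      x.slice(k).cols(lo - pl + j, hi - pl + j));
      dx.slice(k).cols(lo - pl + j, hi - pl + j) +=
          W(j, k) * d_out.slice(k).cols(lo, hi);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW);
}

// Temporal convolution with a shared kernel bank over independent row
// streams (the front-end conv): x is R x T (R = batch*channels streams),
// W is k x F. Same padding, stride 1. Returns out ((R*T) x F), rows
// ordered stream-fastest then time, matching R's column-major reshape.
// im2col + GEMM: the shifted views of the padded buffer are contiguous,
// so building the patch matrix is one pass and the products are BLAS.
// [[Rcpp::export]]
arma::mat conv1_forward_cpp(const arma::mat& x, const arma::mat& W) {
  const int R = x.n_rows, T = x.n_cols, k = W.n_rows;
  const int pl = (k - 1) / 2;
  mat xp(R, T + k - 1, fill::zeros);
  xp.cols(pl, pl + T - 1) = x;
  mat cols(R * T, k);
  for (int j = 0; j < k; ++j)
    std::memcpy(cols.colptr(j), xp.colptr(j), sizeof(double) * R * T);
  return cols * W;
}

// need_dx = false skips the input-gradient half (the front-end conv sits
// directly on the data, so its dx is discarded).
// [[Rcpp::export]]
Rcpp::List conv1_backward_cpp(const arma::mat& d_out, const arma::mat& x,
                              const arma::mat& W, bool need_dx) {
  const int R = x.n_rows, T = x.n_cols, k = W.n_rows;
  const int pl = (k - 1) / 2;
  mat xp(R, T + k - 1, fill::zeros);
  xp.cols(pl, pl + T - 1) = x;
  mat cols(R * T, k);
  for (int j = 0; j < k; ++j)
    std::memcpy(cols.colptr(j), xp.colptr(j), sizeof(double) * R * T);
  mat dW = cols.t() * d_out;
  mat dx;
  if (need_dx) {
    mat dcols = d_out * W.t();
    mat dxp(R, T + k - 1, fill::zeros);
    const size_t n = (size_t)R * T;
    for (int j = 0; j < k; ++j) {
      double* dst = dxp.colptr(j);
      const double* srcv = dcols.colptr(j);
      for (size_t r = 0; r < n; ++r) dst[r] += srcv[r];
    }
    dx = dxp.cols(pl, pl + T - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW);
}

// Depthwise (C,1) convolution collapsing the electrode axis. Input a is
// the temporal-conv activation as a (B*C*T) x F1 matrix (rows ordered
// b, then c, then t fastest-to-slowest as R lays it out); W is C x F1 x
// dm. Output: (B*T) x (F1*dm), out[b + B*t, (f*dm)+m] =
// sum_c a[b + B*c + B*C*t, f] * W(c, f, m).
// [[Rcpp::export]]
arma::mat depthwise_forward_cpp(const arma::mat& a, const arma::cube& W,
                                int B, int C, int T) {
  const int F1 = W.n_cols, dm = W.n_slices;
  mat out(B * T, F1 * dm, fill::zeros);
  for (int f = 0; f < F1; ++f) {
    const double* af = a.colptr(f);
    for (int m = 0; m < dm; ++m) {
      double* of = out.colptr(f * dm + m);
      for (int c = 0; c < C; ++c) {
        const double w = W(c, f, m);
        for (int t = 0; t < T; ++t) {
          const double* src = af + (size_t)B * (c + (size_t)C * t);
          double* dst = of + (size_t)B * t;
          for (int b = 0; b < B; ++b) dst[b] += w * src[b];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List depthwise_backward_cpp(const arma::mat& d_out,
                                  const arma::mat& a, const arma::cube& W,
                                  int B, int C, int T) {
  const int F1 = W.n_cols, dm = W.n_slices;
  mat da(a.n_rows, a.n_cols, fill::zeros);
  cube dW(C, F1, dm, fill::zeros);
  for (int f = 0; f < F1; ++f) {
    const double* af = a.colptr(f);
    double* daf = da.colptr(f);
    for (int m = 0; m < dm; ++m) {
      const double* dof = d_out.colptr(f * dm + m);
      for (int c = 0; c < C; ++c) {
        const double w = W(c, f, m);
        double acc = 0.0;
        for (int t = 0; t < T; ++t) {
          const size_t off = (size_t)B * (c + (size_t)C * t);
          const double* dsrc = dof + (size_t)B * t;
          const double* asrc = af + off;
          double* ddst = daf + off;
          for (int b = 0; b < B; ++b) {
            acc += dsrc[b] * asrc[b];
            ddst[b] += w * dsrc[b];
          }
        }
        dW(c, f, m) = acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("da") = da,
                            Rcpp::Named("dW") = dW);
}

// Column-wise batch-norm application: out = (x - mu) * ivar * gamma +
// beta, also returning xhat = (x - mu) * ivar for the backward pass.
// [[Rcpp::export]]
Rcpp::List bn_apply_cpp(const arma::mat& x, const arma::vec& mu,
                        const arma::vec& ivar, const arma::vec& gamma,
                        const arma::vec& beta) {
  const int n = x.n_rows, F = x.n_cols;
  mat xhat(n, F), out(n, F);
  for (int f = 0; f < F; ++f) {
    const double m = mu(f), iv = ivar(f), g = gamma(f), b = beta(f);
    const double* xc = x.colptr(f);
    double* xh = xhat.colptr(f);
    double* oc = out.colptr(f);
    for (int r = 0; r < n; ++r) {
      xh[r] = (xc[r] - m) * iv;
      oc[r] = xh[r] * g + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat);
}

// Training-mode batch-norm backward (batch moments in the graph).
// [[Rcpp::export]]
Rcpp::List bn_backward_train_cpp(const arma::mat& d_out,
                                 const arma::mat& xhat,
                                 const arma::vec& ivar,
                                 const arma::vec& gamma) {
  const int n = d_out.n_rows, F = d_out.n_cols;
  mat dx(n, F);
  vec dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double* dc = d_out.colptr(f);
    const double* xh = xhat.colptr(f);
    double s1 = 0.0, s2 = 0.0, sb = 0.0;
    for (int r = 0; r < n; ++r) {
      const double dxh = dc[r] * gamma(f);
      s1 += dxh;
      s2 += dxh * xh[r];
      sb += dc[r];
    }
    dgamma(f) = 0.0;
    double dg = 0.0;
    for (int r = 0; r < n; ++r) dg += dc[r] * xh[r];
    dgamma(f) = dg;
    dbeta(f) = sb;
    const double m1 = s1 / n, m2 = s2 / n, g = gamma(f), iv = ivar(f);
    double* dxc = dx.colptr(f);
    for (int r = 0; r < n; ++r)
      dxc[r] = (dc[r] * g - m1 - xh[r] * m2) * iv;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
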