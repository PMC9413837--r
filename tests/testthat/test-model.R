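# The architecture contract: realised tensor shapes at every stage must
# match the published layer table for any valid configuration.
expect_architecture_contract <- function(C, B = 2) {
  cfg <- model_config(C = C, T = 128, n_classes = 2)
  model <- build_model(cfg)
  want <- model_shapes(cfg)
  e2ennet:::with_seed(50 + C, {
    x <- array(rnorm(B * C * 128), c(B, C, 128))
    fw <- e2ennet:::net_forward(model, x, training = FALSE)
    ca <- fw$cache
    # conv stage: (C, T, F1) per batch element
    expect_equal(dim(ca$bn1$xhat), c(B * C * 128, cfg$F1))
    expect_equal(utils::tail(want$conv2d, 1), cfg$F1)
    # depthwise collapses electrodes: (1, T, 2*F1)
    expect_equal(dim(ca$bn2$xhat),
                 c(B * 128, cfg$F1 * cfg$depth_multiplier))
    expect_equal(want$depthwise,
                 c(1L, 128L, cfg$F1 * cfg$depth_multiplier))
    # first pool: (1, T/4, 2*F1)
    expect_equal(dim(ca$sepd_in),
                 c(B, 32, cfg$F1 * cfg$depth_multiplier))
    expect_equal(want$pool1[2], 32)
    # separable output after second pool feeds a F2*(T/32)-step sequence
    expect_equal(dim(ca$bn3$xhat), c(B * 32, cfg$F2))
    expect_equal(dim(ca$lstm[[1]]$xf), c(B * 64, 1))
    expect_equal(want$sequence, c(64L, 1L))
    expect_equal(ca$lstm[[1]]$H, 64)
    expect_equal(dim(ca$lstm[[2]]$xf), c(B * 64, 1))
    expect_equal(ca$lstm[[2]]$H, 32)
    expect_equal(dim(fw$probs), c(B, 2L))
  })
  invisible(TRUE)
}

test_that("every intermediate activation honours the layer table", {
  for (C in c(32L, 14L, 62L)) expect_architecture_contract(C)
})

test_that("depthwise stage always emits depth_multiplier * F1 maps", {
  for (F1 in c(4L, 8L, 16L)) {
    cfg <- model_config(C = 6, T = 64, n_classes = 2, F1 = F1)
    model <- build_model(cfg)
    x <- array(rnorm(2 * 6 * 64), c(2, 6, 64))
    ca <- e2ennet:::net_forward(model, x)$cache
    expect_identical(ncol(ca$bn2$xhat), 2L * F1)
  }
})

test_that("softmax outputs are probability rows for any class count", {
  cfg <- model_config(C = 4, T = 32, n_classes = 7, F1 = 2, F2 = 4,
                      lstm_units = c(6, 5), pool1 = 2, pool2 = 2,
                      temporal_kernel = 8, separable_kernel = 4)
  model <- build_model(cfg)
  e2ennet:::with_seed(51, {
    x <- array(rnorm(5 * 4 * 32), c(5, 4, 32))
    p <- forward(model, x)
    expect_identical(dim(p), c(5L, 7L))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  })
})

test_that("invalid time/pool combinations fail with an explanation", {
  expect_error(model_config(C = 4, T = 100, n_classes = 2),
               "not divisible by pool1\\*pool2")
  expect_error(model_config(C = 4, T = 64, n_classes = 2,
                            lstm_units = c(8, 8, 8, 8)),
               "1 to 3")
})

test_that("batch normalisation matches a two-pass moments oracle", {
  e2ennet:::with_seed(52, {
    x <- matrix(rnorm(200 * 6, mean = 3, sd = 2), 200)
    gamma <- runif(6, 0.5, 2); beta <- rnorm(6)
    got <- batch_normalize(x, gamma, beta, eps = 1e-3)
    oracle <- x
    for (j in 1:6) {
      mu <- mean(x[, j])
      v <- mean((x[, j] - mu)^2)
      oracle[, j] <- (x[, j] - mu) / sqrt(v + 1e-3) * gamma[j] + beta[j]
    }
    expect_equal(got, oracle, tolerance = 1e-12)
    # pre-standardised input: output is roughly scale*x + shift
    z <- matrix(scale(matrix(rnorm(5000), 1000, 5)), 1000, 5)
    zn <- batch_normalize(z, rep(2, 5), rep(1, 5), eps = 1e-8)
    expect_equal(zn, 2 * z * sqrt(1000 / 999) + 1, tolerance = 1e-2)
    # constant batch collapses to the shift
    const <- matrix(5, 50, 3)
    expect_equal(batch_normalize(const, rep(1, 3), rep(0, 3)),
                 matrix(0, 50, 3), tolerance = 1e-9)
    # inference mode uses the provided running moments
    mom <- list(mean = rep(1, 5), var = rep(4, 5))
    zi <- batch_normalize(z, moments = mom, eps = 0)
    expect_equal(zi, (z - 1) / 2, tolerance = 1e-12)
  })
})

test_that("inference output is deterministic and batch-invariant", {
  cfg <- tiny_model_config()
  model <- build_model(cfg)
  e2ennet:::with_seed(53, {
    x <- array(rnorm(4 * 2 * 32), c(4, 2, 32))
    x[2, , ] <- x[1, , ]                 # duplicated input
    p <- forward(model, x)
    expect_equal(p[1, ], p[2, ], tolerance = 1e-12)
    # the same segment scored alone or in company gives the same row
    alone <- forward(model, x[3, , , drop = FALSE])
    expect_equal(alone[1, ], p[3, ], tolerance = 1e-5)
  })
})

test_that("lstm_step implements the printed gate equations", {
  H <- 2; D <- 3
  zero_w <- list(W_xi = matrix(0, D, H), W_hi = matrix(0, H, H),
                 W_xg = matrix(0, D, H), W_hg = matrix(0, H, H),
                 W_xc = matrix(0, D, H), W_hc = matrix(0, H, H),
                 W_xo = matrix(0, D, H), W_ho = matrix(0, H, H),
                 b_i = rep(0, H), b_g = rep(0, H), b_c = rep(0, H),
                 b_o = rep(0, H), W_ci = rep(0, H), W_cg = rep(0, H),
                 W_co = rep(0, H))
  st <- lstm_step(rep(1, D), list(h = rep(0, H), c = rep(0, H)), zero_w)
  expect_equal(st$h, rep(0, H))          # all-zero weights -> zero output

  # saturation: huge gate pre-activations drive every gate to 1, so
  # c_t -> c_{t-1} + tanh(x W_xc + b_c)
  sat_w <- zero_w
  sat_w$b_i <- rep(50, H); sat_w$b_g <- rep(50, H); sat_w$b_o <- rep(50, H)
  sat_w$W_xc <- matrix(0.3, D, H)
  c0 <- c(0.4, -0.2)
  st <- lstm_step(rep(1, D), list(h = rep(0, H), c = c0), sat_w)
  expect_equal(st$c, c0 + tanh(rep(0.9, H)), tolerance = 1e-12)
  expect_equal(st$h, tanh(st$c), tolerance = 1e-12)
})

test_that("the batched LSTM equals a hand-unrolled recurrence oracle", {
  H <- 2; D <- 1; S <- 3; B <- 2
  e2ennet:::with_seed(54, {
    w <- e2ennet:::lstm_init(D, H, peephole = TRUE)
    w$p_i <- runif(H, -0.5, 0.5)
    w$p_g <- runif(H, -0.5, 0.5)
    w$p_o <- runif(H, -0.5, 0.5)
    uw <- e2ennet:::lstm_unpack(w)
    x <- array(rnorm(B * S * D), c(B, S, D))

    # oracle: plain-R scalar unroll of the printed equations
    sig <- function(z) 1 / (1 + exp(-z))
    h_or <- matrix(0, B, H); c_or <- matrix(0, B, H)
    for (t in seq_len(S)) {
      for (b in seq_len(B)) {
        xt <- x[b, t, ]
        i <- sig(xt %*% uw$W_xi + h_or[b, ] %*% uw$W_hi +
                   c_or[b, ] * uw$W_ci + uw$b_i)
        g <- sig(xt %*% uw$W_xg + h_or[b, ] %*% uw$W_hg +
                   c_or[b, ] * uw$W_cg + uw$b_g)
        cb <- tanh(xt %*% uw$W_xc + h_or[b, ] %*% uw$W_hc + uw$b_c)
        cn <- g * c_or[b, ] + i * cb
        o <- sig(xt %*% uw$W_xo + h_or[b, ] %*% uw$W_ho +
                   cn * uw$W_co + uw$b_o)
        c_or[b, ] <- cn
        h_or[b, ] <- o * tanh(cn)
      }
    }
    got <- e2ennet:::lstm_forward(x, w)
    expect_equal(got$h, h_or, tolerance = 1e-6)

    # lstm_step agrees step by step as well
    st <- list(h = rep(0, H), c = rep(0, H))
    for (t in seq_len(S)) st <- lstm_step(x[1, t, ], st, uw)
    expect_equal(st$h, h_or[1, ], tolerance = 1e-6)
  })
})

test_that("cross-entropy equals the direct per-row sum", {
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(cross_entropy_loss(perfect, c(0L, 1L)), 0)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(uniform, c(0L, 1L, 1L, 0L)), log(2),
               tolerance = 1e-12)
  e2ennet:::with_seed(55, {
    z <- matrix(runif(6 * 3), 6)
    p <- z / rowSums(z)
    y <- sample(0:2, 6, replace = TRUE)
    oracle <- -mean(vapply(1:6, function(i) log(p[i, y[i] + 1]), 0))
    expect_equal(cross_entropy_loss(p, y), oracle, tolerance = 1e-12)
    expect_gte(cross_entropy_loss(p, y), 0)
  })
})

test_that("separable-convolution cost ratio equals explicit multiply counts", {
  expect_equal(conv_cost_ratio(3, 8), 1 / 8 + 1 / 9, tolerance = 1e-12)
  expect_equal(conv_cost_ratio(1, 1), 2)
  # oracle: literally count multiplications of both convolution styles
  count_standard <- function(Sf, Sk, M, N) {
    n <- 0
    for (k in seq_len(Sf)) for (l in seq_len(Sf))
      for (i in seq_len(Sk)) for (j in seq_len(Sk))
        for (m in seq_len(M)) for (nn in seq_len(N)) n <- n + 1
    n
  }
  count_separable <- function(Sf, Sk, M, N) {
    n <- 0
    for (k in seq_len(Sf)) for (l in seq_len(Sf))      # depthwise
      for (i in seq_len(Sk)) for (j in seq_len(Sk))
        for (m in seq_len(M)) n <- n + 1
    for (k in seq_len(Sf)) for (l in seq_len(Sf))      # pointwise
      for (m in seq_len(M)) for (nn in seq_len(N)) n <- n + 1
    n
  }
  for (cfg in list(c(8, 3, 4, 8), c(4, 2, 3, 5), c(5, 1, 2, 7))) {
    Sf <- cfg[1]; Sk <- cfg[2]; M <- cfg[3]; N <- cfg[4]
    ratio <- count_separable(Sf, Sk, M, N) / count_standard(Sf, Sk, M, N)
    expect_equal(conv_cost_ratio(Sk, N), ratio, tolerance = 1e-12)
  }
})

test_that("parameter counts match per-layer arithmetic", {
  cfg <- model_config(C = 14, T = 128, n_classes = 2)
  model <- build_model(cfg)
  # hand calculation, layer by layer (convs are bias-free, BN has
  # scale+shift, peephole LSTMs add three vectors per layer)
  conv1 <- 64 * 8
  bn1 <- 2 * 8
  dw <- 14 * 8 * 2
  bn2 <- 2 * 16
  sepd <- 16 * 16
  sepp <- 16 * 16
  bn3 <- 2 * 16
  lstm1 <- 1 * 4 * 64 + 64 * 4 * 64 + 4 * 64 + 3 * 64
  lstm2 <- 1 * 4 * 32 + 32 * 4 * 32 + 4 * 32 + 3 * 32
  dense <- 32 * 2 + 2
  expect_equal(count_parameters(model),
               conv1 + bn1 + dw + bn2 + sepd + sepp + bn3 +
                 lstm1 + lstm2 + dense)
  # monotone in F1; conv-free variant drops all convolution parameters
  bigger <- build_model(model_config(C = 14, T = 128, n_classes = 2,
                                     F1 = 16))
  expect_gt(count_parameters(bigger), count_parameters(model))
  lstm_only <- build_model(model_config(C = 14, T = 128, n_classes = 2,
                                        variant = "no_conv"))
  expect_null(lstm_only$params$conv1)
})

test_that("ablation variants build and run with coherent shapes", {
  e2ennet:::with_seed(56, {
    x <- array(rnorm(3 * 4 * 64), c(3, 4, 64))
    for (v in c("no_conv", "no_lstm")) {
      cfg <- model_config(C = 4, T = 64, n_classes = 2, F1 = 4, F2 = 8,
                          temporal_kernel = 16, separable_kernel = 8,
                          variant = v)
      model <- build_model(cfg)
      p <- forward(model, x)
      expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    }
    for (lu in list(16L, c(16L, 8L), c(16L, 8L, 4L))) {
      cfg <- model_config(C = 4, T = 64, n_classes = 2, F1 = 4, F2 = 8,
                          temporal_kernel = 16, separable_kernel = 8,
                          lstm_units = lu)
      p <- forward(build_model(cfg), x)
      expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    }
  })
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config()
  model <- build_model(cfg)
  e2ennet:::with_seed(57, {
    x <- array(rnorm(3 * 2 * 32), c(3, 2, 32))
    y <- c(0L, 1L, 0L)
  })
  lg <- e2ennet:::net_loss_grads(model, x, y, training = TRUE)
  fd <- function(path, idx, eps = 1e-6) {
    m2 <- model
    v <- pluck_path(m2$params, path)
    v[idx] <- v[idx] + eps
    m2$params <- poke_path(m2$params, path, v)
    up <- e2ennet:::net_loss_grads(m2, x, y, training = TRUE)$loss
    v[idx] <- v[idx] - 2 * eps
    m2$params <- poke_path(m2$params, path, v)
    dn <- e2ennet:::net_loss_grads(m2, x, y, training = TRUE)$loss
    (up - dn) / (2 * eps)
  }
  paths <- list(list("conv1"), list("bn1", "gamma"), list("bn1", "beta"),
                list("dw"), list("bn2", "gamma"), list("sepd"),
                list("sepp"), list("bn3", "beta"),
                list("lstm", 1, "Wx"), list("lstm", 1, "Wh"),
                list("lstm", 1, "b"), list("lstm", 1, "p_i"),
                list("lstm", 1, "p_g"), list("lstm", 2, "Wh"),
                list("lstm", 2, "p_o"), list("dense", "W"),
                list("dense", "b"))
  for (pa in paths) {
    g <- pluck_path(lg$grads, pa)
    for (idx in unique(c(1L, length(g)))) {
      num <- fd(pa, idx)
      ana <- as.numeric(g)[idx]
      # relative agreement, with an absolute floor where the gradient is
      # itself at finite-difference noise level
      expect_true(abs(num - ana) <= 1e-4 * max(abs(num), abs(ana), 1e-4),
                  label = sprintf("gradient of %s[%d] (fd %.3e vs %.3e)",
                                  paste(unlist(pa), collapse = "/"),
                                  idx, num, ana))
    }
  }
})

test_that("gradients also check out for the conv-free and LSTM-free variants", {
  e2ennet:::with_seed(58, {
    x <- array(rnorm(2 * 3 * 32), c(2, 3, 32))
    y <- c(1L, 0L)
    for (v in c("no_conv", "no_lstm")) {
      cfg <- model_config(C = 3, T = 32, n_classes = 2, F1 = 2, F2 = 4,
                          lstm_units = c(4, 3), dropout_p = 0,
                          temporal_kernel = 8, separable_kernel = 4,
                          variant = v, seed = 17)
      model <- build_model(cfg)
      lg <- e2ennet:::net_loss_grads(model, x, y, training = TRUE)
      path <- if (v == "no_conv") list("lstm", 1, "Wx") else list("sepp")
      g <- pluck_path(lg$grads, path)
      eps <- 1e-6
      m2 <- model
      vv <- pluck_path(m2$params, path)
      vv[1] <- vv[1] + eps
      m2$params <- poke_path(m2$params, path, vv)
      up <- e2ennet:::net_loss_grads(m2, x, y, training = TRUE)$loss
      vv[1] <- vv[1] - 2 * eps
      m2$params <- poke_path(m2$params, path, vv)
      dn <- e2ennet:::net_loss_grads(m2, x, y, training = TRUE)$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(as.numeric(g)[1], num, tolerance = 1e-4)
    }
  })
})
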