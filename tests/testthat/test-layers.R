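test_that("conv1d matches identity, bias-only and brute-force cases", {
  idk <- array(c(0, 1, 0), c(3, 1, 1))
  expect_equal(conv1d_forward(matrix(1:4), idk, 0), matrix(1:4 + 0))
  zk <- array(0, c(3, 1, 2))
  expect_equal(conv1d_forward(matrix(1:4), zk, c(5, 2)),
               cbind(rep(5, 4), rep(2, 4)))
  set.seed(10)
  for (i in 1:100) {
    sl <- sample(6:12, 1); nf <- sample(1:4, 1); infeat <- sample(1:3, 1)
    ksz <- sample(c(1, 3, 5), 1)
    x <- matrix(rnorm(sl * infeat), sl)
    k <- array(rnorm(ksz * infeat * nf), c(ksz, infeat, nf))
    b <- rnorm(nf)
    expect_equal(conv1d_forward(x, k, b), oracle_conv1d(x, k, b),
                 tolerance = 1e-5)
  }
  expect_error(conv1d_forward(matrix(1:2), idk, 0), "shorter")
})

test_that("maxpool1d matches window maxima and drops the remainder", {
  expect_equal(maxpool1d(matrix(c(1, 3, 2, 5)), 2), matrix(c(3, 5)))
  expect_equal(maxpool1d(matrix(7, 6, 2), 3), matrix(7, 2, 2))
  set.seed(11)
  for (i in 1:100) {
    sl <- sample(5:13, 1); nc <- sample(1:5, 1); pool <- sample(2:4, 1)
    if (sl < pool) next
    x <- matrix(rnorm(sl * nc), sl)
    expect_equal(maxpool1d(x, pool), oracle_maxpool(x, pool),
                 tolerance = 1e-12)
  }
  expect_error(maxpool1d(matrix(1:4), 0), "pool")
})

test_that("SE squeeze, excitation and scaling match direct evaluation", {
  expect_equal(se_squeeze(matrix(2, 3, 1)), 2)
  expect_equal(se_squeeze(matrix(1:3)), 2)
  set.seed(12)
  u <- matrix(rnorm(8 * 4), 8)
  expect_equal(se_squeeze(u), apply(u, 2, mean), tolerance = 1e-12)

  # zero weights: sigmoid(0) exactly
  expect_equal(se_excite(rnorm(4), matrix(0, 2, 4), matrix(0, 4, 2)),
               rep(0.5, 4), tolerance = 1e-9)
  for (i in 1:100) {
    z <- rnorm(4, 0, 3)
    W1 <- matrix(rnorm(8), 2); W2 <- matrix(rnorm(8), 4)
    s <- se_excite(z, W1, W2)
    expect_true(all(s > 0 & s < 1))
    h <- as.vector(W1 %*% z); h <- ifelse(h > 0, h, exp(h) - 1)
    expect_equal(s, as.vector(1 / (1 + exp(-W2 %*% h))), tolerance = 1e-5)
  }
  expect_error(se_excite(rnorm(3), matrix(0, 2, 4), matrix(0, 4, 2)),
               "shapes")

  expect_equal(se_scale(u, rep(1, 4)), u)
  expect_true(all(se_scale(u, rep(0, 4)) == 0))
  s <- runif(4)
  expect_equal(se_scale(u, s), u * rep(s, each = 8), tolerance = 1e-12)
})

test_that("lstm_step reproduces closed-form and hand-computed cases", {
  z0 <- function(n_hid, n_in) {
    m <- matrix(0, n_hid, n_hid + n_in)
    list(w_i = m, w_f = m, w_o = m, w_g = m, b_i = numeric(n_hid),
         b_f = numeric(n_hid), b_o = numeric(n_hid), b_g = numeric(n_hid))
  }
  st <- lstm_step(rnorm(2), rnorm(3), numeric(3), z0(3, 2))
  expect_equal(st$c, numeric(3))
  expect_equal(st$h, numeric(3))
  cprev <- c(-1, 0.5, 2)
  st <- lstm_step(rnorm(2), rnorm(3), cprev, z0(3, 2))
  expect_equal(st$c, 0.5 * cprev, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * cprev), tolerance = 1e-12)

  # scalar unit, all weights 1, biases 0, x = 1, h_prev = C_prev = 0
  p1 <- list(w_i = matrix(1, 1, 2), w_f = matrix(1, 1, 2),
             w_o = matrix(1, 1, 2), w_g = matrix(1, 1, 2),
             b_i = 0, b_f = 0, b_o = 0, b_g = 0)
  st <- lstm_step(1, 0, 0, p1)
  sg <- 1 / (1 + exp(-1))
  expect_equal(st$c, sg * tanh(1), tolerance = 1e-12)   # ~0.5568
  expect_equal(st$h, sg * tanh(sg * tanh(1)), tolerance = 1e-12)  # ~0.3695
  expect_equal(st$c, 0.5568, tolerance = 1e-3)
  expect_equal(st$h, 0.3695, tolerance = 1e-3)
})

test_that("bilstm_forward is symmetric on palindromes and chains lstm_step", {
  p <- random_lstm_params(3, 2, seed = 5)
  x <- rbind(c(1, -1), c(0.5, 2), c(1, -1))   # palindromic rows
  out <- bilstm_forward(x, p, p, merge = "concat")
  expect_equal(out[, 1:3], out[nrow(x):1, 4:6], tolerance = 1e-12)

  # gated merge with zero gate weights
  g <- bilstm_forward(x, p, p, merge = "gated",
                      W_h = matrix(0, 3, 6), b_h = numeric(3))
  expect_true(all(abs(g - 0.5) < 1e-12))

  # two-step scalar sequence vs manual unrolling
  p1 <- random_lstm_params(1, 1, seed = 6)
  x1 <- matrix(c(0.3, -0.8))
  s1 <- lstm_step(x1[1, ], 0, 0, p1)
  s2 <- lstm_step(x1[2, ], s1$h, s1$c, p1)
  r1 <- lstm_step(x1[2, ], 0, 0, p1)
  r2 <- lstm_step(x1[1, ], r1$h, r1$c, p1)
  expect_equal(bilstm_forward(x1, p1, p1),
               cbind(c(s1$h, s2$h), c(r2$h, r1$h)), tolerance = 1e-12)
})

test_that("batched Bi-LSTM kernel agrees with the per-sample reference", {
  set.seed(20)
  for (i in 1:20) {
    U <- sample(1:4, 1); C <- sample(2:9, 1); n <- sample(1:6, 1)
    pf <- random_lstm_params(U, 1, seed = i)
    pb <- random_lstm_params(U, 1, seed = i + 100)
    kf <- pack_lstm_params(pf); kb <- pack_lstm_params(pb)
    x <- matrix(rnorm(n * C), n)
    bi <- dacb:::bilstm_forward_cpp(x, kf$W, kf$b, kb$W, kb$b)
    for (s in seq_len(n)) {
      ref <- bilstm_forward(matrix(x[s, ]), pf, pb, merge = "concat")
      got <- t(bi$H[s, , ])                      # seq x 2U
      expect_equal(got, ref, tolerance = 1e-5)
    }
  }
})

test_that("dot-product attention yields a probability vector and known cases", {
  set.seed(13)
  # zero scores: uniform weights, output = column mean
  V <- matrix(rnorm(12), 4)
  at <- dot_attention(V, W_a = matrix(0, 3, 3), q = rep(1, 3))
  expect_equal(at$d, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(at$a, colMeans(V), tolerance = 1e-9)

  for (i in 1:100) {
    V <- matrix(rnorm(8), 2)
    at <- dot_attention(V, matrix(rnorm(16), 4), rnorm(4))
    expect_equal(sum(at$d), 1, tolerance = 1e-6)
    expect_true(all(at$d >= 0))
  }

  # 2x2 identity case, evaluated directly from the defining equations
  at <- dot_attention(diag(2), diag(2), c(1, 0))
  d_exp <- exp(c(tanh(1), 0)) / sum(exp(c(tanh(1), 0)))
  expect_equal(at$d, d_exp, tolerance = 1e-9)
  expect_equal(round(at$d, 3), c(0.682, 0.318))
  expect_equal(at$a, as.vector(d_exp %*% diag(2)), tolerance = 1e-9)
})
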