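test_that("model configuration validates its counts", {
  expect_error(model_config(8, 3, conv_filters = 10, se_reduction = 4),
               "divisible")
  expect_error(model_config(2, 3, conv_kernel = 3), "conv_kernel")
  expect_s3_class(tiny_cfg(), "ModelConfig")
})

test_that("forward pass produces probability rows, equivariantly", {
  cfg <- tiny_cfg(seed = 2)
  p <- init_dacb_params(cfg)
  set.seed(3)
  x <- matrix(rnorm(40 * 8), 40)
  pr <- dacb_forward(x, p, cfg)
  expect_equal(dim(pr), c(40L, 3L))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 40), tolerance = 1e-6)

  perm <- sample(40)
  expect_equal(dacb_forward(x[perm, ], p, cfg), pr[perm, ],
               tolerance = 1e-12)
  expect_error(dacb_forward(x[, 1:5], p, cfg), "n_channels")
})

test_that("batched forward equals the composition of the layer operations", {
  cfg <- model_config(n_channels = 6, n_classes = 2, conv_filters = 4,
                      se_reduction = 2, lstm_units = 2, fc1_units = 4,
                      fc2_units = 3, proj_units = 3, seed = 8)
  p <- init_dacb_params(cfg)
  lstm_ref <- function(W, b, u) {
    # unpack the (U+1) x 4U kernel layout into the reference gate lists
    list(w_i = t(W[, 1:u, drop = FALSE]),
         w_f = t(W[, (u + 1):(2 * u), drop = FALSE]),
         w_g = t(W[, (2 * u + 1):(3 * u), drop = FALSE]),
         w_o = t(W[, (3 * u + 1):(4 * u), drop = FALSE]),
         b_i = b[1:u], b_f = b[(u + 1):(2 * u)],
         b_g = b[(2 * u + 1):(3 * u)], b_o = b[(3 * u + 1):(4 * u)])
  }
  reference_forward <- function(xrow) {
    # spatial branch
    a <- conv1d_forward(matrix(xrow), p$conv_W, p$conv_b)
    pl <- maxpool1d(a, cfg$pool_size)
    z <- se_squeeze(pl)
    s <- se_excite(z, p$se_W1, p$se_W2)
    v_s <- as.vector(se_scale(pl, s)) %*% p$projs_W + p$projs_b
    # temporal branch
    pf <- lstm_ref(p$lstm_fw_W, p$lstm_fw_b, cfg$lstm_units)
    pb <- lstm_ref(p$lstm_bw_W, p$lstm_bw_b, cfg$lstm_units)
    hseq <- bilstm_forward(matrix(xrow), pf, pb, merge = "concat")
    v_t <- as.vector(t(hseq)) %*% p$projt_W + p$projt_b
    # attention fusion and head
    at <- dot_attention(rbind(v_s, v_t), p$attn_Wa, p$attn_q)
    h1 <- pmax(at$a %*% p$fc1_W + p$fc1_b, 0)
    h2 <- pmax(h1 %*% p$fc2_W + p$fc2_b, 0)
    logit <- h2 %*% p$out_W + p$out_b
    exp(logit - max(logit)) / sum(exp(logit - max(logit)))
  }
  set.seed(9)
  x <- matrix(rnorm(5 * 6), 5)
  got <- dacb_forward(x, p, cfg)
  for (i in 1:5)
    expect_equal(got[i, ], as.vector(reference_forward(x[i, ])),
                 tolerance = 1e-6)
})

test_that("SE weights and attention weights stay in their ranges", {
  cfg <- tiny_cfg(seed = 31)
  p <- init_dacb_params(cfg)
  for (sd in 1:5) {
    set.seed(sd)
    x <- matrix(rnorm(30 * 8, 0, 3), 30)
    fwd <- dacb:::dacb_forward_batch(x, p, cfg, want_cache = TRUE)
    s <- fwd$cache$sp$cache$s
    expect_true(all(s > 0 & s < 1))
    D <- fwd$cache$fu$D
    expect_true(all(D >= 0))
    expect_equal(rowSums(D), rep(1, 30), tolerance = 1e-6)
  }
  # a zero query scores both branches equally: uniform attention, so the
  # fused vector is the plain average of the branch features
  p0 <- p; p0$attn_q <- p$attn_q * 0
  fwd <- dacb:::dacb_forward_batch(matrix(rnorm(80), 10), p0, cfg,
                                   want_cache = TRUE)
  expect_true(all(abs(fwd$cache$fu$D - 0.5) < 1e-12))
  expect_equal(fwd$cache$a, (fwd$cache$sp$v + fwd$cache$tp$v) / 2,
               tolerance = 1e-12)
})

test_that("ablation variants carry only their branch's weights", {
  cfg <- tiny_cfg()
  b1 <- build_ablation_variant(cfg, "block1_spatial_only")
  expect_false(any(grepl("lstm|projt|merge", names(b1$params))))
  expect_true(any(grepl("conv", names(b1$params))))
  b2 <- build_ablation_variant(cfg, "block2_temporal_only")
  expect_false(any(grepl("conv|se_|projs", names(b2$params))))
  expect_true(any(grepl("lstm", names(b2$params))))
  full <- build_ablation_variant(cfg, "full")
  set.seed(1)
  x <- matrix(rnorm(6 * 8), 6)
  expect_equal(predict_dacb(full, x),
               max.col(dacb_forward(x, full$params, full$cfg),
                       ties.method = "first") - 1L)
  expect_equal(dacb_forward(x, full$params, full$cfg),
               dacb_forward(x, init_dacb_params(cfg), cfg))
  # single-branch forwards are valid probability rows too
  for (m in list(b1, b2)) {
    pr <- dacb_forward(x, m$params, m$cfg)
    expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-6)
  }
  expect_error(build_ablation_variant(cfg, "both"), "arg")
})

test_that("position-mode attention and gated merge forwards are well-formed", {
  for (cfg in list(tiny_cfg(attention_mode = "position"),
                   tiny_cfg(bilstm_merge = "gated"))) {
    p <- init_dacb_params(cfg)
    x <- matrix(rnorm(12 * 8), 12)
    pr <- dacb_forward(x, p, cfg)
    expect_equal(rowSums(pr), rep(1, 12), tolerance = 1e-6)
  }
})

test_that("training reduces cross-entropy and fits separable data", {
  skip_if_not_installed("MASS")
  batch <- make_blob_batch(n = 600, n_channels = 8, n_classes = 4, seed = 4)
  # linear-probe baseline: the task is genuinely learnable
  probe <- MASS::lda(batch$x, grouping = batch$y)
  expect_gt(mean(predict(probe, batch$x)$class == batch$y), 0.9)

  cfg <- tiny_cfg(n_channels = 8, n_classes = 4, seed = 7)
  tcfg <- train_config(epochs = 25, learning_rate = 0.005,
                       batch_size = 64, seed = 7)
  m <- train_dacb(dacb_model(cfg), batch, tcfg)
  expect_equal(nrow(m$history), 25)
  expect_gt(m$history$accuracy[25], 0.9)
  expect_lt(m$history$loss[25], m$history$loss[1])
  # monotone decrease over epoch averages, within 5% slack
  expect_true(all(diff(m$history$loss) < 0.05 * m$history$loss[-25]))
})

test_that("training is deterministic and validates its inputs", {
  batch <- make_blob_batch(n = 200, n_classes = 3, seed = 5)
  cfg <- tiny_cfg(n_channels = 8, n_classes = 3, seed = 3)
  tcfg <- train_config(epochs = 3, batch_size = 64, seed = 9)
  m1 <- train_dacb(dacb_model(cfg), batch, tcfg)
  m2 <- train_dacb(dacb_model(cfg), batch, tcfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  bad <- batch; bad$n_classes <- 5L
  expect_error(train_dacb(dacb_model(cfg), bad, tcfg), "class count")
})
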