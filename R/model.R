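#' Model configuration for the dual-branch network
#'
#' Architecture hyperparameters: the spatial branch is Conv1d(64, kernel 3,
#' same padding, ReLU) -> max pool (2) -> SE attention (reduction `r`) ->
#' flatten; the temporal branch is a Bi-LSTM (32 units per direction) ->
#' flatten; both branch vectors are linearly projected to `proj_units` and
#' fused by tanh-keyed dot-product attention; the head is Dense(64, ReLU) ->
#' Dense(32, ReLU) -> softmax over `n_classes`.
#'
#' @param n_channels electrodes per sample (sequence length of the network
#'   input; each sample is one timepoint's channel vector).
#' @param n_classes number of output classes.
#' @param conv_filters number of convolution filters (default 64).
#' @param conv_kernel convolution kernel size (default 3).
#' @param pool_size max-pooling window (default 2).
#' @param se_reduction SE bottleneck reduction ratio r (default 8); must
#'   divide `conv_filters`.
#' @param lstm_units hidden units per LSTM direction (default 32).
#' @param fc1_units,fc2_units dense head widths (defaults 64, 32).
#' @param proj_units common width both branch vectors are projected to
#'   before attention fusion (default 64).
#' @param attention_mode `"branch"` (attention over the two branch vectors,
#'   the default) or `"position"` (attention weights over the flattened
#'   feature positions, applied as an elementwise reweighting).
#' @param bilstm_merge `"concat"` (per-step concatenation of forward and
#'   backward states, the default) or `"gated"` (learned sigmoid gate over
#'   the concatenation).
#' @param variant `"full"`, `"block1_spatial_only"` (conv+SE branch only) or
#'   `"block2_temporal_only"` (Bi-LSTM branch only).
#' @param seed integer seed for parameter initialization.
#' @return a `ModelConfig` object.
#' @export
model_config <- function(n_channels, n_classes, conv_filters = 64,
                         conv_kernel = 3, pool_size = 2, se_reduction = 8,
                         lstm_units = 32, fc1_units = 64, fc2_units = 32,
                         proj_units = 64,
                         attention_mode = c("branch", "position"),
                         bilstm_merge = c("concat", "gated"),
                         variant = c("full", "block1_spatial_only",
                                     "block2_temporal_only"),
                         seed = 42) {
  attention_mode <- match.arg(attention_mode)
  bilstm_merge <- match.arg(bilstm_merge)
  variant <- match.arg(variant)
  counts <- c(n_channels, n_classes, conv_filters, conv_kernel, pool_size,
              se_reduction, lstm_units, fc1_units, fc2_units, proj_units)
  if (any(counts < 1)) stop("all ModelConfig counts must be at least 1")
  if (conv_filters %% se_reduction != 0)
    stop("conv_filters must be divisible by se_reduction")
  if (n_channels < conv_kernel)
    stop("n_channels must be at least conv_kernel")
  if (n_channels < pool_size)
    stop("n_channels must be at least pool_size")
  structure(list(
    n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
    conv_filters = as.integer(conv_filters),
    conv_kernel = as.integer(conv_kernel), pool_size = as.integer(pool_size),
    se_reduction = as.integer(se_reduction),
    lstm_units = as.integer(lstm_units), fc1_units = as.integer(fc1_units),
    fc2_units = as.integer(fc2_units), proj_units = as.integer(proj_units),
    attention_mode = attention_mode, bilstm_merge = bilstm_merge,
    variant = variant, seed = as.integer(seed)
  ), class = "ModelConfig")
}

has_spatial <- function(cfg) cfg$variant != "block2_temporal_only"
has_temporal <- function(cfg) cfg$variant != "block1_spatial_only"

# Widths of the flattened branch outputs and the fused vector.
branch_widths <- function(cfg) {
  wp <- cfg$n_channels %/% cfg$pool_size
  flat_s <- wp * cfg$conv_filters
  flat_t <- cfg$n_channels *
    (if (cfg$bilstm_merge == "concat") 2L else 1L) * cfg$lstm_units
  n_branches <- has_spatial(cfg) + has_temporal(cfg)
  fused <- if (cfg$attention_mode == "position" && n_branches == 2L)
    2L * cfg$proj_units else cfg$proj_units
  list(pooled = wp, flat_s = flat_s, flat_t = flat_t, fused = fused,
       n_branches = n_branches)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize all learnable weights of the network
#'
#' Seeded uniform initialization with fan-in/fan-out scaling
#' (Glorot-uniform) for every weight matrix, zero biases except the LSTM
#' forget-gate bias, which starts at 1 so early training does not flush the
#' cell state. Only components present in the configured variant are
#' allocated: single-branch ablations carry no weights of the removed
#' branch.
#'
#' @param cfg a [model_config()].
#' @return flat named list of parameter arrays (`DACBParams`).
#' @export
init_dacb_params <- function(cfg) {
  w <- branch_widths(cfg)
  u <- cfg$lstm_units
  with_seed(cfg$seed, {
    p <- list()
    if (has_spatial(cfg)) {
      p$conv_W <- array(glorot(cfg$conv_kernel, cfg$conv_filters),
                        c(cfg$conv_kernel, 1L, cfg$conv_filters))
      p$conv_b <- numeric(cfg$conv_filters)
      nred <- cfg$conv_filters %/% cfg$se_reduction
      p$se_W1 <- glorot(nred, cfg$conv_filters)
      p$se_W2 <- glorot(cfg$conv_filters, nred)
      p$projs_W <- glorot(w$flat_s, cfg$proj_units)
      p$projs_b <- numeric(cfg$proj_units)
    }
    if (has_temporal(cfg)) {
      for (dir in c("fw", "bw")) {
        W <- glorot(u + 1L, 4L * u)
        b <- numeric(4L * u)
        b[(u + 1L):(2L * u)] <- 1   # forget gate
        p[[paste0("lstm_", dir, "_W")]] <- W
        p[[paste0("lstm_", dir, "_b")]] <- b
      }
      if (cfg$bilstm_merge == "gated") {
        p$merge_Wh <- glorot(u, 2L * u)
        p$merge_bh <- numeric(u)
      }
      p$projt_W <- glorot(w$flat_t, cfg$proj_units)
      p$projt_b <- numeric(cfg$proj_units)
    }
    if (w$n_branches == 2L) {
      if (cfg$attention_mode == "branch") {
        p$attn_Wa <- glorot(cfg$proj_units, cfg$proj_units)
        p$attn_q <- as.vector(glorot(cfg$proj_units, 1L))
      } else {
        p$attn_Wa <- glorot(1L, 1L)
        p$attn_q <- as.vector(glorot(1L, 1L))
      }
    }
    p$fc1_W <- glorot(w$fused, cfg$fc1_units)
    p$fc1_b <- numeric(cfg$fc1_units)
    p$fc2_W <- glorot(cfg$fc1_units, cfg$fc2_units)
    p$fc2_b <- numeric(cfg$fc2_units)
    p$out_W <- glorot(cfg$fc2_units, cfg$n_classes)
    p$out_b <- numeric(cfg$n_classes)
    p
  })
}

#' Construct a model (configuration plus initialized parameters)
#'
#' @param cfg a [model_config()].
#' @return a `DACBModel`: list with `cfg` and `params`.
#' @export
dacb_model <- function(cfg) {
  stopifnot(inherits(cfg, "ModelConfig"))
  structure(list(cfg = cfg, params = init_dacb_params(cfg)),
            class = "DACBModel")
}

#' Build a full or single-branch ablation variant
#'
#' `block1_spatial_only` keeps the conv+SE branch only (attention over a
#' single branch vector degenerates to the identity), and its parameter set
#' contains no LSTM weights; `block2_temporal_only` keeps the Bi-LSTM branch
#' only, with no conv or SE weights; `full` is the complete network.
#'
#' @param cfg a [model_config()].
#' @param variant `"block1_spatial_only"`, `"block2_temporal_only"` or
#'   `"full"`.
#' @return a `DACBModel`.
#' @export
build_ablation_variant <- function(cfg, variant = c("full",
                                                    "block1_spatial_only",
                                                    "block2_temporal_only")) {
  variant <- match.arg(variant)
  cfg$variant <- variant
  dacb_model(cfg)
}

# Shift the columns of a matrix by d (positive d pulls later columns
# forward), zero-filling vacated positions.
shift_cols <- function(x, d) {
  n <- nrow(x); m <- ncol(x)
  y <- matrix(0, n, m)
  if (d >= 0) {
    if (d < m) y[, seq_len(m - d)] <- x[, (1 + d):m, drop = FALSE]
  } else if (-d < m) {
    y[, (1 - d):m] <- x[, seq_len(m + d), drop = FALSE]
  }
  y
}

# --- batched forward -------------------------------------------------------

# Spatial branch forward on an n x C input matrix; returns the projected
# branch vector and the cache needed for backpropagation. Heavy stages
# (conv/ReLU/pool, SE scaling) run in compiled kernels; maps are kept in
# position-major flat form ((n*wp) x filters).
spatial_forward <- function(x, p, cfg, w) {
  n <- nrow(x); F <- cfg$conv_filters
  Wmat <- matrix(p$conv_W, cfg$conv_kernel, F)
  cp <- conv_pool_fwd_cpp(x, Wmat, p$conv_b, cfg$pool_size)
  z <- cp$z
  h_pre <- z %*% t(p$se_W1)
  h <- elu(h_pre)
  e <- h %*% t(p$se_W2)
  s <- sigmoid(e)                                   # n x F, in (0,1)
  scaled <- se_scale_fwd_cpp(cp$cache, s)
  # scaled is (n*wp) x F position-major, so the flat view is a plain reshape
  flat <- matrix(scaled, n, w$pooled * F)
  v <- sweep(flat %*% p$projs_W, 2, p$projs_b, "+")
  list(v = v, cache = list(x = x, sptr = cp$cache, z = z,
                           h_pre = h_pre, h = h, s = s, flat = flat))
}

spatial_backward <- function(dv, p, cfg, w, cache, n) {
  F <- cfg$conv_filters; wp <- w$pooled
  g <- list()
  g$projs_W <- t(cache$flat) %*% dv
  g$projs_b <- colSums(dv)
  dscaled <- matrix(dv %*% t(p$projs_W), n * wp, F)
  ds <- se_scale_bwd_cpp(cache$sptr, dscaled, cache$s)
  # through excitation
  de <- ds * cache$s * (1 - cache$s)
  g$se_W2 <- t(de) %*% cache$h
  dh <- de %*% p$se_W2
  dh_pre <- dh * elu_grad(cache$h_pre)
  g$se_W1 <- t(dh_pre) %*% cache$z
  dz <- dh_pre %*% p$se_W1
  squeeze_bwd_add_cpp(cache$sptr, dz)
  cb <- conv_pool_bwd_cpp(cache$sptr, cache$x, cfg$pool_size,
                          cfg$conv_kernel)
  release_spatial_cache_cpp(cache$sptr)
  g$conv_W <- array(cb$dW, c(cfg$conv_kernel, 1L, F))
  g$conv_b <- as.vector(cb$db)
  g
}

# Temporal branch forward; x is n x C, treated as a length-C sequence of
# scalar inputs per sample. The bidirectional recurrence runs in a fused
# compiled kernel returning the per-step [h_fw, h_bw] concatenation.
temporal_forward <- function(x, p, cfg, w) {
  n <- nrow(x); C <- ncol(x); u <- cfg$lstm_units
  bi <- bilstm_forward_cpp(x, p$lstm_fw_W, p$lstm_fw_b,
                           p$lstm_bw_W, p$lstm_bw_b)
  cache <- list(x = x, H = bi$H, ptr = bi$cache)
  if (cfg$bilstm_merge == "gated") {
    HH <- matrix(aperm(bi$H, c(1, 3, 2)), n * C, 2L * u)
    Gpre <- sweep(HH %*% t(p$merge_Wh), 2, p$merge_bh, "+")
    G <- sigmoid(Gpre)
    merged <- aperm(array(G, c(n, C, u)), c(1, 3, 2))
    cache$HH <- HH; cache$G <- G
    flat <- matrix(merged, n, u * C)
  } else {
    flat <- matrix(bi$H, n, 2L * u * C)
  }
  cache$flat <- flat
  v <- sweep(flat %*% p$projt_W, 2, p$projt_b, "+")
  list(v = v, cache = cache)
}

temporal_backward <- function(dv, p, cfg, w, cache, n) {
  C <- cfg$n_channels; u <- cfg$lstm_units
  g <- list()
  g$projt_W <- t(cache$flat) %*% dv
  g$projt_b <- colSums(dv)
  dflat <- dv %*% t(p$projt_W)
  if (cfg$bilstm_merge == "gated") {
    dmerged <- array(dflat, c(n, u, C))
    dG <- matrix(aperm(dmerged, c(1, 3, 2)), n * C, u)
    dGpre <- dG * cache$G * (1 - cache$G)
    g$merge_Wh <- t(dGpre) %*% cache$HH
    g$merge_bh <- colSums(dGpre)
    dHH <- dGpre %*% p$merge_Wh
    dHcat <- aperm(array(dHH, c(n, C, 2L * u)), c(1, 3, 2))
  } else {
    dHcat <- array(dflat, c(n, 2L * u, C))
  }
  bb <- bilstm_backward_cpp(cache$ptr, cache$x, p$lstm_fw_W, p$lstm_bw_W,
                            cache$H, dHcat)
  release_bilstm_cache_cpp(cache$ptr)
  g$lstm_fw_W <- bb$dWf; g$lstm_fw_b <- as.vector(bb$dbf)
  g$lstm_bw_W <- bb$dWb; g$lstm_bw_b <- as.vector(bb$dbb)
  g
}

# Attention fusion of the two projected branch vectors (n x P each).
# Branch mode stacks them as a 2-row value matrix per sample; position mode
# treats each of the 2P scalar features as one value position and applies
# the resulting weights as an elementwise reweighting (scaled by the
# position count to keep magnitudes comparable).
fusion_forward <- function(v1, v2, p, cfg) {
  n <- nrow(v1)
  if (cfg$attention_mode == "branch") {
    K1 <- tanh(v1 %*% p$attn_Wa); K2 <- tanh(v2 %*% p$attn_Wa)
    S <- cbind(as.vector(K1 %*% p$attn_q), as.vector(K2 %*% p$attn_q))
    D <- row_softmax(S)
    a <- D[, 1] * v1 + D[, 2] * v2
    list(a = a, D = D, cache = list(K1 = K1, K2 = K2, D = D))
  } else {
    vcat <- cbind(v1, v2)
    K <- tanh(vcat * p$attn_Wa[1, 1])
    D <- row_softmax(K * p$attn_q[1])
    a <- ncol(vcat) * D * vcat
    list(a = a, D = D, cache = list(vcat = vcat, K = K, D = D))
  }
}

fusion_backward <- function(da, v1, v2, p, cfg, cache) {
  D <- cache$D
  if (cfg$attention_mode == "branch") {
    dv1 <- D[, 1] * da
    dv2 <- D[, 2] * da
    dd1 <- rowSums(da * v1); dd2 <- rowSums(da * v2)
    # softmax over the two positions
    dot <- dd1 * D[, 1] + dd2 * D[, 2]
    ds1 <- D[, 1] * (dd1 - dot); ds2 <- D[, 2] * (dd2 - dot)
    dK1 <- outer(ds1, p$attn_q); dK2 <- outer(ds2, p$attn_q)
    dq <- colSums(ds1 * cache$K1) + colSums(ds2 * cache$K2)
    dA1 <- dK1 * (1 - cache$K1^2); dA2 <- dK2 * (1 - cache$K2^2)
    dWa <- t(v1) %*% dA1 + t(v2) %*% dA2
    dv1 <- dv1 + dA1 %*% t(p$attn_Wa)
    dv2 <- dv2 + dA2 %*% t(p$attn_Wa)
    list(dv1 = dv1, dv2 = dv2, attn_Wa = dWa, attn_q = dq)
  } else {
    vcat <- cache$vcat; K <- cache$K
    m <- ncol(vcat)
    dD <- m * da * vcat
    dvcat <- m * da * D
    ds <- D * (dD - rowSums(dD * D))          # softmax backward, row-wise
    dq <- sum(ds * K)
    dK <- ds * p$attn_q[1]
    dpre <- dK * (1 - K^2)
    dWa <- sum(dpre * vcat)
    dvcat <- dvcat + dpre * p$attn_Wa[1, 1]
    P <- ncol(v1)
    list(dv1 = dvcat[, seq_len(P), drop = FALSE],
         dv2 = dvcat[, P + seq_len(P), drop = FALSE],
         attn_Wa = matrix(dWa, 1, 1), attn_q = dq)
  }
}

# Full batched forward pass. Returns class probabilities and, when
# want_cache, every intermediate needed by dacb_backward.
dacb_forward_batch <- function(x, p, cfg, want_cache = FALSE) {
  w <- branch_widths(cfg)
  n <- nrow(x)
  sp <- if (has_spatial(cfg)) spatial_forward(x, p, cfg, w)
  tp <- if (has_temporal(cfg)) temporal_forward(x, p, cfg, w)
  if (w$n_branches == 2L) {
    fu <- fusion_forward(sp$v, tp$v, p, cfg)
    a <- fu$a
  } else {
    # single-branch ablation: attention over one value row is the identity
    fu <- NULL
    a <- if (has_spatial(cfg)) sp$v else tp$v
  }
  h1_pre <- sweep(a %*% p$fc1_W, 2, p$fc1_b, "+")
  h1 <- relu(h1_pre)
  h2_pre <- sweep(h1 %*% p$fc2_W, 2, p$fc2_b, "+")
  h2 <- relu(h2_pre)
  logits <- sweep(h2 %*% p$out_W, 2, p$out_b, "+")
  probs <- row_softmax(logits)
  if (!want_cache) {
    # free the compiled-side caches immediately so the next forward call
    # reuses their heap blocks rather than faulting in fresh pages
    if (!is.null(sp)) release_spatial_cache_cpp(sp$cache$sptr)
    if (!is.null(tp)) release_bilstm_cache_cpp(tp$cache$ptr)
    return(list(probs = probs))
  }
  list(probs = probs,
       cache = list(x = x, w = w, sp = sp, tp = tp, fu = fu, a = a,
                    h1_pre = h1_pre, h1 = h1, h2_pre = h2_pre, h2 = h2))
}

#' Forward pass of the network
#'
#' Maps a batch of samples (rows are channel vectors) to class
#' probabilities; each output row is non-negative and sums to one.
#'
#' @param x n x n_channels numeric matrix, or a `SampleBatch`.
#' @param params parameter list from [init_dacb_params()].
#' @param cfg the matching [model_config()].
#' @return n x n_classes probability matrix.
#' @export
dacb_forward <- function(x, params, cfg) {
  if (inherits(x, "SampleBatch")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != cfg$n_channels)
    stop("input width does not match cfg$n_channels")
  dacb_forward_batch(x, params, cfg)$probs
}

# Gradient of mean categorical cross-entropy w.r.t. every parameter.
# y_onehot is n x n_classes; returns grads named like the parameter list.
dacb_backward <- function(p, cfg, cache, probs, y_onehot) {
  n <- nrow(probs)
  g <- list()
  dlogits <- (probs - y_onehot) / n
  g$out_W <- t(cache$h2) %*% dlogits
  g$out_b <- colSums(dlogits)
  dh2 <- (dlogits %*% t(p$out_W)) * (cache$h2_pre > 0)
  g$fc2_W <- t(cache$h1) %*% dh2
  g$fc2_b <- colSums(dh2)
  dh1 <- (dh2 %*% t(p$fc2_W)) * (cache$h1_pre > 0)
  g$fc1_W <- t(cache$a) %*% dh1
  g$fc1_b <- colSums(dh1)
  da <- dh1 %*% t(p$fc1_W)
  w <- cache$w
  if (w$n_branches == 2L) {
    fb <- fusion_backward(da, cache$sp$v, cache$tp$v, p, cfg, cache$fu$cache)
    g$attn_Wa <- fb$attn_Wa; g$attn_q <- fb$attn_q
    dv_s <- fb$dv1; dv_t <- fb$dv2
  } else {
    dv_s <- da; dv_t <- da
  }
  if (has_spatial(cfg))
    g <- c(g, spatial_backward(dv_s, p, cfg, w, cache$sp$cache, n))
  if (has_temporal(cfg))
    g <- c(g, temporal_backward(dv_t, p, cfg, w, cache$tp$cache, n))
  g
}

#' Class predictions for a batch
#'
#' Runs the forward pass in memory-bounded chunks and takes the argmax of
#' each probability row, breaking ties toward the lowest class index.
#'
#' @param model a `DACBModel`.
#' @param batch a `SampleBatch` or numeric matrix.
#' @param chunk maximum rows per forward pass.
#' @return integer vector of predicted classes in `0:(n_classes - 1)`.
#' @export
predict_dacb <- function(model, batch, chunk = 4096L) {
  x <- if (inherits(batch, "SampleBatch")) batch$x else as.matrix(batch)
  n <- nrow(x)
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    pr <- dacb_forward_batch(x[idx, , drop = FALSE], model$params,
                             model$cfg)$probs
    out[idx] <- max.col(pr, ties.method = "first") - 1L
  }
  out
}
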