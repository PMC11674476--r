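#' 1D convolution (cross-correlation) with same padding and ReLU
#'
#' Single-sample spatial-branch convolution: stride 1, zero same-padding,
#' one output map per filter, followed by ReLU.
#'
#' @param x seq_len x in_features numeric matrix.
#' @param kernels array of dim (kernel_size, in_features, n_filters).
#' @param biases numeric vector of length n_filters.
#' @return seq_len x n_filters matrix.
#' @export
conv1d_forward <- function(x, kernels, biases) {
  x <- as.matrix(x)
  ksz <- dim(kernels)[1]; infeat <- dim(kernels)[2]; nf <- dim(kernels)[3]
  if (ncol(x) != infeat) stop("input feature count does not match kernels")
  if (nrow(x) < ksz) stop("sequence shorter than the convolution kernel")
  lpad <- (ksz - 1) %/% 2
  n <- nrow(x)
  xp <- rbind(matrix(0, lpad, infeat), x, matrix(0, ksz - 1 - lpad, infeat))
  out <- matrix(0, n, nf)
  for (f in seq_len(nf)) {
    acc <- rep(biases[f], n)
    for (k in seq_len(ksz))
      for (j in seq_len(infeat))
        acc <- acc + xp[(k):(k + n - 1), j] * kernels[k, j, f]
    out[, f] <- acc
  }
  relu(out)
}

#' Non-overlapping 1D max pooling
#'
#' @param x seq_len x c matrix of feature maps (columns).
#' @param pool window size; trailing remainder positions are dropped.
#' @return floor(seq_len / pool) x c matrix of window maxima.
#' @export
maxpool1d <- function(x, pool) {
  x <- as.matrix(x)
  if (pool < 1) stop("pool size must be at least 1")
  if (nrow(x) < pool) stop("sequence shorter than the pooling window")
  n_out <- nrow(x) %/% pool
  out <- matrix(-Inf, n_out, ncol(x))
  for (k in seq_len(pool))
    out <- pmax(out, x[seq(k, by = pool, length.out = n_out), , drop = FALSE])
  out
}

#' SE squeeze: global average pooling per feature map
#'
#' @param u W x c matrix (columns are feature maps of length W).
#' @return length-c vector of per-map means.
#' @export
se_squeeze <- function(u) colMeans(as.matrix(u))

#' SE excitation: two-layer bottleneck with ELU and sigmoid
#'
#' Computes `sigmoid(W2 %*% elu(W1 %*% z))`; the reduction layer W1 maps c
#' maps to c/r hidden units and the expansion layer W2 maps back to c
#' per-map weights, each strictly inside (0, 1).
#'
#' @param z length-c squeeze vector.
#' @param W1 (c/r) x c reduction weights.
#' @param W2 c x (c/r) expansion weights.
#' @return length-c weight vector in (0, 1).
#' @export
se_excite <- function(z, W1, W2) {
  if (ncol(W1) != length(z) || ncol(W2) != nrow(W1) || nrow(W2) != length(z))
    stop("SE weight shapes inconsistent with the squeeze vector")
  as.vector(sigmoid(W2 %*% elu(W1 %*% z)))
}

#' SE scale: reweight feature maps
#'
#' @param u W x c matrix of feature maps.
#' @param s length-c weight vector.
#' @return W x c matrix with column c multiplied by `s[c]`.
#' @export
se_scale <- function(u, s) {
  u <- as.matrix(u)
  if (ncol(u) != length(s)) stop("weight length does not match map count")
  sweep(u, 2, s, "*")
}

#' One LSTM cell step
#'
#' Reference (single-sample) implementation of the gated recurrence: forget,
#' input and output gates through the logistic sigmoid, tanh candidate,
#' `C_t = f * C_prev + i * g`, `h_t = o * tanh(C_t)`. Gate weights act on the
#' concatenation `[h_prev, x_t]`.
#'
#' @param x_t input vector at the current step.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @param p list with gate weight matrices `w_i`, `w_f`, `w_g`, `w_o`
#'   (each n_hid x (n_hid + n_in)) and biases `b_i`, `b_f`, `b_g`, `b_o`.
#' @return list with `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, p) {
  z <- c(h_prev, x_t)
  if (ncol(p$w_f) != length(z)) stop("gate weights do not match [h, x] length")
  f <- sigmoid(as.vector(p$w_f %*% z) + p$b_f)
  i <- sigmoid(as.vector(p$w_i %*% z) + p$b_i)
  o <- sigmoid(as.vector(p$w_o %*% z) + p$b_o)
  g <- tanh(as.vector(p$w_g %*% z) + p$b_g)
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

# Run one direction over a seq_len x in_features input, returning the
# seq_len x n_hid hidden-state sequence.
lstm_run <- function(x, p) {
  n_hid <- length(p$b_f)
  h <- numeric(n_hid); cc <- numeric(n_hid)
  out <- matrix(0, nrow(x), n_hid)
  for (t in seq_len(nrow(x))) {
    st <- lstm_step(x[t, ], h, cc, p)
    h <- st$h; cc <- st$c
    out[t, ] <- h
  }
  out
}

#' Bidirectional LSTM over one sample
#'
#' Runs a forward LSTM over `t = 1..T` and a backward LSTM over the reversed
#' input. With `merge = "concat"` each step yields `[h_fw_t, h_bw_t]`
#' (seq_len x 2*n_hid); with `merge = "gated"` the concatenation is passed
#' through a learned sigmoid gate `sigmoid(W_h [h_fw, h_bw] + b_h)`
#' (seq_len x n_hid).
#'
#' @param x seq_len x in_features matrix.
#' @param p_fw,p_bw forward/backward LSTM parameter lists (see [lstm_step()]).
#' @param merge `"concat"` or `"gated"`.
#' @param W_h,b_h gate weights (n_hid x 2*n_hid) and bias, gated merge only.
#' @return hidden-state sequence matrix.
#' @export
bilstm_forward <- function(x, p_fw, p_bw, merge = c("concat", "gated"),
                           W_h = NULL, b_h = NULL) {
  merge <- match.arg(merge)
  x <- as.matrix(x)
  h_fw <- lstm_run(x, p_fw)
  h_bw <- lstm_run(x[rev(seq_len(nrow(x))), , drop = FALSE], p_bw)
  h_bw <- h_bw[rev(seq_len(nrow(x))), , drop = FALSE]  # align to input steps
  out <- cbind(h_fw, h_bw)
  if (merge == "gated") {
    if (is.null(W_h) || is.null(b_h)) stop("gated merge needs W_h and b_h")
    out <- t(sigmoid(W_h %*% t(out) + b_h))
  }
  out
}

#' Dot-product attention with tanh-projected keys
#'
#' Keys are `K = tanh(V %*% W_a)`; scores are the inner products of the
#' learned query with each key row, softmax-normalized into a probability
#' vector `d`; the output is the weighted combination `a = d %*% V`.
#'
#' @param V n_positions x d_v value matrix.
#' @param W_a d_v x d_k key projection matrix.
#' @param q length-d_k query vector.
#' @return list with `a` (length-d_v fused vector) and `d` (n_positions
#'   attention weights, non-negative, summing to 1).
#' @export
dot_attention <- function(V, W_a, q) {
  V <- as.matrix(V)
  if (ncol(V) != nrow(W_a)) stop("W_a rows must match value width")
  if (length(q) != ncol(W_a)) stop("query length must match key width")
  K <- tanh(V %*% W_a)
  s <- as.vector(K %*% q)
  d <- as.vector(row_softmax(matrix(s, 1)))
  list(a = as.vector(d %*% V), d = d)
}
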