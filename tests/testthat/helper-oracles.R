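# Brute-force layer oracles, written independently of the implementation
# and shared by the unit and acceptance suites.

oracle_conv1d <- function(x, kernels, biases) {
  ksz <- dim(kernels)[1]; nf <- dim(kernels)[3]
  lpad <- (ksz - 1) %/% 2
  n <- nrow(x)
  out <- matrix(0, n, nf)
  for (f in seq_len(nf)) for (t in seq_len(n)) {
    acc <- biases[f]
    for (k in seq_len(ksz)) {
      src <- t + (k - 1) - lpad
      if (src >= 1 && src <= n)
        acc <- acc + sum(x[src, ] * kernels[k, , f])
    }
    out[t, f] <- max(acc, 0)
  }
  out
}

oracle_maxpool <- function(x, pool) {
  n_out <- nrow(x) %/% pool
  out <- matrix(0, n_out, ncol(x))
  for (j in seq_len(ncol(x))) for (t in seq_len(n_out))
    out[t, j] <- max(x[((t - 1) * pool + 1):(t * pool), j])
  out
}

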