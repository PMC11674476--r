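# Shared fixtures, all generated in code.

# Small model configuration so unit tests stay fast.
tiny_cfg <- function(n_channels = 8, n_classes = 3, ...) {
  model_config(n_channels = n_channels, n_classes = n_classes,
               conv_filters = 8, se_reduction = 4, lstm_units = 4,
               fc1_units = 10, fc2_units = 6, proj_units = 5, ...)
}

# Linearly separable Gaussian blobs as a SampleBatch: class c lives along a
# random unit direction with offset, plus isotropic noise.
make_blob_batch <- function(n = 400, n_channels = 8, n_classes = 4,
                            noise = 0.15, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * n_channels), n_classes)
  centers <- centers / sqrt(rowSums(centers^2)) * 2
  y <- rep_len(seq_len(n_classes) - 1L, n)
  x <- centers[y + 1L, ] + matrix(rnorm(n * n_channels, 0, noise), n)
  sample_batch(x, y, subject_id = rep_len(1:4, n),
               trial_id = rep_len(1:20, n), n_classes = n_classes)
}

# Small synthetic trial set for pipeline tests.
small_spec <- function(n_subjects = 6, n_trials = 8, n_channels = 12,
                       trial_length = 60, segment_length = 40,
                       n_classes = 4, snr = 25, seed = 11, ...) {
  synth_spec(n_subjects, n_trials, n_channels, trial_length, segment_length,
             n_classes, snr = snr, seed = seed, ...)
}

# Random LSTM parameter list for the per-sample reference implementation.
random_lstm_params <- function(n_hid, n_in, seed = 1) {
  set.seed(seed)
  m <- function() matrix(rnorm(n_hid * (n_hid + n_in), 0, 0.5), n_hid)
  list(w_i = m(), w_f = m(), w_o = m(), w_g = m(),
       b_i = rnorm(n_hid, 0, 0.2), b_f = rnorm(n_hid, 0, 0.2),
       b_o = rnorm(n_hid, 0, 0.2), b_g = rnorm(n_hid, 0, 0.2))
}

# Convert the reference parameter list to the packed (U+1+?) x 4U matrix
# used by the batched kernels (gate column order i, f, g, o; rows = [h, x]).
pack_lstm_params <- function(p) {
  W <- t(rbind(p$w_i, p$w_f, p$w_g, p$w_o))
  b <- c(p$b_i, p$b_f, p$b_g, p$b_o)
  list(W = W, b = b)
}
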