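#' Specification for a synthetic EEG trial set
#'
#' Describes a labelled multichannel synthetic EEG corpus with the sample
#' structure of the SEED-IV (15 subjects x 24 clips, 62 channels, 4 emotion
#' classes) or DREAMER (23 subjects x 18 clips, 14 channels, three 5-class
#' valence/arousal/dominance ratings) datasets. Generation is a pure function
#' of the spec, including its seed.
#'
#' Each class receives a signature consisting of a unit-norm channel-gain
#' vector (spatial structure) and an oscillation parameter set (temporal
#' structure). A trial of class \eqn{c} is
#' \deqn{X = g_c \, w_c(t)^\top + \epsilon, \quad
#'       w_c(t) = a_0 + \sum_k a_k \sin(2\pi f_k t + \phi_k),}
#' with i.i.d. Gaussian noise scaled so that
#' \code{mean(signal^2) / sigma^2 = snr}. The baseline term \eqn{a_0}
#' exceeds \eqn{\sum_k a_k}, so the instantaneous spatial pattern never
#' vanishes and every per-timepoint sample carries class information.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_subject clips per subject.
#' @param n_channels electrodes per trial (62 for SEED-IV emulation, 14 for
#'   DREAMER emulation); at least 2.
#' @param trial_length timepoints per trial; at least `segment_length`.
#' @param segment_length length of the centred segment later extracted from
#'   each trial (default 1000).
#' @param n_classes classes per label dimension (4 or 5 for the emulated
#'   datasets); at least 2.
#' @param label_mode `"single"` for one categorical label per trial
#'   (SEED-IV style) or `"vad_triple"` for three independent labels per
#'   trial (DREAMER valence/arousal/dominance style).
#' @param snr dimensionless signal-to-noise ratio (signal power over noise
#'   variance).
#' @param seed integer seed; identical specs produce bit-identical output.
#' @param gain_groups optional integer vector (length `n_classes`, values in
#'   `0:(n_classes-1)`) assigning classes to shared channel-gain signatures;
#'   defaults to one gain per class. Used to construct data whose class
#'   information is split between spatial and oscillatory structure.
#' @param osc_groups optional integer vector assigning classes to shared
#'   oscillation signatures; defaults to one per class.
#' @return an object of class `SynthSpec`.
#' @seealso [generate_trialset()], [synth_spec_seediv()],
#'   [synth_spec_dreamer()]
#' @export
synth_spec <- function(n_subjects, n_trials_per_subject, n_channels,
                       trial_length, segment_length = 1000, n_classes,
                       label_mode = c("single", "vad_triple"), snr = 10,
                       seed = 42, gain_groups = NULL, osc_groups = NULL) {
  label_mode <- match.arg(label_mode)
  stopifnot(n_subjects >= 1, n_trials_per_subject >= 1)
  if (n_channels < 2) stop("n_channels must be at least 2")
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (trial_length < segment_length)
    stop("trial_length must be >= segment_length")
  if (snr <= 0) stop("snr must be positive")
  gain_groups <- gain_groups %||% seq_len(n_classes) - 1L
  osc_groups <- osc_groups %||% seq_len(n_classes) - 1L
  if (length(gain_groups) != n_classes || length(osc_groups) != n_classes)
    stop("gain_groups and osc_groups must have one entry per class")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    n_channels = as.integer(n_channels),
    trial_length = as.integer(trial_length),
    segment_length = as.integer(segment_length),
    n_classes = as.integer(n_classes),
    label_mode = label_mode,
    snr = snr,
    seed = as.integer(seed),
    gain_groups = as.integer(gain_groups),
    osc_groups = as.integer(osc_groups)
  ), class = "SynthSpec")
}

#' SEED-IV-shaped synthetic preset
#'
#' 15 subjects x 24 clips, 62 channels, 4 classes, one label per trial.
#'
#' @param trial_length,segment_length trial and extracted-segment lengths.
#' @param snr signal-to-noise ratio.
#' @param seed integer seed.
#' @param ... further arguments passed to [synth_spec()].
#' @export
synth_spec_seediv <- function(trial_length = 3000, segment_length = 1000,
                              snr = 10, seed = 42, ...) {
  synth_spec(n_subjects = 15, n_trials_per_subject = 24, n_channels = 62,
             trial_length = trial_length, segment_length = segment_length,
             n_classes = 4, label_mode = "single", snr = snr, seed = seed, ...)
}

#' DREAMER-shaped synthetic preset
#'
#' 23 subjects x 18 clips, 14 channels, three independent 5-class labels
#' (valence, arousal, dominance) per trial.
#'
#' @inheritParams synth_spec_seediv
#' @export
synth_spec_dreamer <- function(trial_length = 3000, segment_length = 1000,
                               snr = 10, seed = 42, ...) {
  synth_spec(n_subjects = 23, n_trials_per_subject = 18, n_channels = 14,
             trial_length = trial_length, segment_length = segment_length,
             n_classes = 5, label_mode = "vad_triple", snr = snr, seed = seed,
             ...)
}

# Draw all class signatures for one label dimension. Gain vectors are drawn
# per gain group and redrawn until all pairwise cosines are < 0.9, so
# distinct groups are geometrically distinguishable even at low channel
# counts; oscillation sets differ across osc groups in frequency content and
# overall amplitude. Deterministic given (seed, dimension).
class_signatures <- function(n_classes, n_channels, seed,
                             gain_groups = seq_len(n_classes) - 1L,
                             osc_groups = seq_len(n_classes) - 1L,
                             dimension = 0L) {
  gg <- unique(gain_groups)
  og <- unique(osc_groups)
  with_seed(derive_seed(seed, 7919L + dimension), {
    gains <- list()
    for (g in gg) {
      for (attempt in 1:1000) {
        v <- rnorm(n_channels)
        v <- v / sqrt(sum(v^2))
        ok <- all(vapply(gains, function(u) abs(sum(u * v)) < 0.9, logical(1)))
        if (ok) break
      }
      if (!ok) stop("could not draw gain vectors with pairwise cosine < 0.9")
      gains[[as.character(g)]] <- v
    }
    oscs <- list()
    for (o in og) {
      n_comp <- 3L
      amps <- runif(n_comp, 0.5, 1.5) * (1 + 0.5 * match(o, og))
      oscs[[as.character(o)]] <- list(
        freqs = runif(n_comp, 0.01, 0.15),   # cycles per timepoint
        amps = amps,
        phases = runif(n_comp, 0, 2 * pi),
        baseline = 1.25 * sum(amps)
      )
    }
    lapply(seq_len(n_classes) - 1L, function(cl) {
      osc <- oscs[[as.character(osc_groups[cl + 1L])]]
      c(list(gain = gains[[as.character(gain_groups[cl + 1L])]]), osc)
    })
  })
}

#' Class signature: channel gains and oscillation parameters
#'
#' Returns the spatial (unit-norm channel-gain vector) and temporal
#' (oscillation frequencies, amplitudes, phases, and baseline) signature of
#' one class. Signatures of distinct classes have pairwise cosine similarity
#' below 0.9 between their gain vectors.
#'
#' @param class_id class index in `0:(n_classes - 1)`.
#' @param n_channels number of channels.
#' @param seed integer seed shared by all classes of one generator.
#' @param n_classes total number of classes the signature set is drawn for.
#' @return list with elements `gain` (unit-norm length-`n_channels` vector),
#'   `freqs`, `amps`, `phases` (per oscillation component) and `baseline`.
#' @export
make_class_signature <- function(class_id, n_channels, seed, n_classes = 4L) {
  if (class_id < 0 || class_id >= n_classes)
    stop("class_id must lie in [0, n_classes)")
  class_signatures(n_classes, n_channels, seed)[[class_id + 1L]]
}

# Deterministic class waveform over timepoints 1..len.
class_waveform <- function(sig, len) {
  t <- seq_len(len)
  w <- rep(sig$baseline, len)
  for (k in seq_along(sig$freqs))
    w <- w + sig$amps[k] * sin(2 * pi * sig$freqs[k] * t + sig$phases[k])
  w
}

# Noise-free channel x time template for one class (one label dimension).
class_template <- function(sig, len) outer(sig$gain, class_waveform(sig, len))

#' Generate a labelled synthetic trial set
#'
#' Produces `n_subjects * n_trials_per_subject` trials of shape
#' `n_channels x trial_length`. Labels are balanced across classes up to
#' rounding and assigned by a seeded permutation; in `vad_triple` mode the
#' three label dimensions are balanced and permuted independently, and the
#' trial signal is the equal-weight sum of the three dimension templates.
#'
#' @param spec a [synth_spec()] object.
#' @return a `TrialSet`: list with `trials` (list of channel x time
#'   matrices), `labels` (integer vector, or n x 3 integer matrix in
#'   `vad_triple` mode), `subject_id`, `clip_id`, `n_channels`, `n_classes`,
#'   `label_mode`.
#' @export
generate_trialset <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$n_subjects * spec$n_trials_per_subject
  n_dim <- if (spec$label_mode == "vad_triple") 3L else 1L
  sigs <- lapply(seq_len(n_dim) - 1L, function(d)
    class_signatures(spec$n_classes, spec$n_channels, spec$seed,
                     spec$gain_groups, spec$osc_groups, dimension = d))
  with_seed(spec$seed, {
    labels <- vapply(seq_len(n_dim), function(d)
      sample(rep_len(seq_len(spec$n_classes) - 1L, n)), integer(n))
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      signal <- matrix(0, spec$n_channels, spec$trial_length)
      for (d in seq_len(n_dim))
        signal <- signal +
          class_template(sigs[[d]][[labels[i, d] + 1L]], spec$trial_length)
      if (n_dim > 1L) signal <- signal / sqrt(n_dim)
      sigma <- sqrt(mean(signal^2) / spec$snr)
      trials[[i]] <- signal +
        matrix(rnorm(length(signal), 0, sigma), nrow(signal))
    }
    structure(list(
      trials = trials,
      labels = if (n_dim == 1L) labels[, 1L] else labels,
      subject_id = rep(seq_len(spec$n_subjects),
                       each = spec$n_trials_per_subject),
      clip_id = rep(seq_len(spec$n_trials_per_subject), spec$n_subjects),
      n_channels = spec$n_channels,
      n_classes = spec$n_classes,
      label_mode = spec$label_mode
    ), class = "TrialSet")
  })
}

#' @export
print.TrialSet <- function(x, ...) {
  cat(sprintf(
    "TrialSet: %d trials (%d subjects), %d channels x %d timepoints, %s\n",
    length(x$trials), length(unique(x$subject_id)), x$n_channels,
    ncol(x$trials[[1]]),
    if (x$label_mode == "single")
      sprintf("%d classes", x$n_classes)
    else
      sprintf("3 x %d-class labels (valence/arousal/dominance)", x$n_classes)))
  invisible(x)
}
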