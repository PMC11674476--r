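#' Write a trial set to a directory
#'
#' Stores one RDS file per subject (list with `eeg` trial matrices, `labels`,
#' `clip_id`) plus a JSON manifest recording the layout, channel count, class
#' count and file list.
#'
#' @param trialset a `TrialSet`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_trials <- function(trialset, dir) {
  stopifnot(inherits(trialset, "TrialSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sort(unique(trialset$subject_id))
  files <- character(0)
  lab <- as.matrix(trialset$labels)
  for (s in subjects) {
    idx <- which(trialset$subject_id == s)
    f <- sprintf("subject_%03d.rds", s)
    saveRDS(list(eeg = trialset$trials[idx],
                 labels = lab[idx, , drop = FALSE],
                 clip_id = trialset$clip_id[idx]),
            file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- list(layout = "synthetic_dir",
                   n_subjects = length(subjects),
                   n_channels = trialset$n_channels,
                   n_classes = trialset$n_classes,
                   label_mode = trialset$label_mode,
                   subject_ids = subjects,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a trial set from disk
#'
#' `synthetic_dir` reads the directory layout produced by [write_trials()]
#' (per-subject RDS files plus `manifest.json`). The `seediv_mat` and
#' `dreamer_mat` layouts name the on-disk organisation of the
#' permission-gated SEED-IV and DREAMER MAT-file distributions; no MAT
#' reader is bundled, so these layouts raise an error describing the
#' expected conversion to the `synthetic_dir` layout.
#'
#' @param path directory containing the trial store.
#' @param layout one of `"synthetic_dir"`, `"seediv_mat"`, `"dreamer_mat"`.
#' @return a `TrialSet`.
#' @export
read_trials <- function(path,
                        layout = c("synthetic_dir", "seediv_mat",
                                   "dreamer_mat")) {
  layout <- match.arg(layout)
  if (layout != "synthetic_dir")
    stop(sprintf(
      paste0("layout '%s' refers to the MAT-file distribution of a ",
             "permission-gated dataset; convert each subject to the ",
             "'synthetic_dir' layout (subject_###.rds files with fields ",
             "eeg/labels/clip_id plus manifest.json) and reload"), layout))
  if (!dir.exists(path)) stop(sprintf("directory '%s' does not exist", path))
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf(paste0("no manifest.json in '%s'; expected a manifest and ",
                        "subject_###.rds files as written by write_trials()"),
                 path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  trials <- list(); labels <- NULL; subject_id <- integer(0)
  clip_id <- integer(0)
  for (i in seq_along(manifest$files)) {
    f <- file.path(path, manifest$files[i])
    if (!file.exists(f)) stop(sprintf("manifest names missing file '%s'", f))
    rec <- readRDS(f)
    if (any(vapply(rec$eeg, nrow, 0L) != manifest$n_channels))
      stop(sprintf("channel-count mismatch in '%s': expected %d channels",
                   f, manifest$n_channels))
    trials <- c(trials, rec$eeg)
    labels <- rbind(labels, rec$labels)
    subject_id <- c(subject_id, rep(manifest$subject_ids[i], length(rec$eeg)))
    clip_id <- c(clip_id, rec$clip_id)
  }
  structure(list(
    trials = trials,
    labels = if (ncol(labels) == 1L) as.integer(labels[, 1L]) else labels,
    subject_id = subject_id,
    clip_id = clip_id,
    n_channels = manifest$n_channels,
    n_classes = manifest$n_classes,
    label_mode = manifest$label_mode
  ), class = "TrialSet")
}

#' Extract the centred segment of a trial
#'
#' Returns `n` consecutive columns from the middle of a channel x time
#' matrix, starting at column `floor((L - n) / 2) + 1` (floor centring).
#'
#' @param trial channel x time numeric matrix.
#' @param n segment length in timepoints (default 1000).
#' @return channel x `n` matrix.
#' @export
extract_middle_segment <- function(trial, n = 1000) {
  len <- ncol(trial)
  if (len < n)
    stop(sprintf("trial has %d timepoints; segment of %d requested", len, n))
  start <- (len - n) %/% 2
  trial[, (start + 1):(start + n), drop = FALSE]
}

#' Build per-timepoint samples from fixed-length segments
#'
#' Each timepoint of each segment becomes one model sample: a length-C
#' channel vector, treated downstream as a sequence of C scalar features.
#' Samples inherit their trial's label(s) and subject identifier, so a
#' trial set with `m` segments of length `n` yields `m * n` samples.
#'
#' @param trialset a `TrialSet` whose trials all share one length (e.g.
#'   after [extract_middle_segment()]).
#' @param label_dim which label dimension to attach in `vad_triple` mode
#'   (1 = valence, 2 = arousal, 3 = dominance).
#' @return a `SampleBatch`: list with `x` (n_samples x n_channels matrix),
#'   `y` (integer classes), `subject_id`, `trial_id`, `n_classes`.
#' @export
slice_timepoint_samples <- function(trialset, label_dim = 1L) {
  stopifnot(inherits(trialset, "TrialSet"))
  lens <- vapply(trialset$trials, ncol, 0L)
  if (length(unique(lens)) != 1L)
    stop("segments have ragged lengths; extract fixed-length segments first")
  n <- lens[1]
  lab <- as.matrix(trialset$labels)[, label_dim]
  x <- t(do.call(cbind, trialset$trials))   # (m*n) x C, timepoints stacked
  sample_batch(
    x = x,
    y = rep(as.integer(lab), each = n),
    subject_id = rep(trialset$subject_id, each = n),
    trial_id = rep(seq_along(trialset$trials), each = n),
    n_classes = trialset$n_classes
  )
}

#' Construct a SampleBatch
#'
#' @param x n_samples x n_channels numeric matrix (each row one sample, the
#'   channel vector of one timepoint).
#' @param y integer class labels in `0:(n_classes - 1)`.
#' @param subject_id integer subject per sample.
#' @param trial_id integer source-trial index per sample.
#' @param n_classes number of classes.
#' @export
sample_batch <- function(x, y, subject_id = rep(1L, length(y)),
                         trial_id = rep(1L, length(y)), n_classes) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y disagree in sample count")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  if (any(y < 0L | y >= n_classes)) stop("labels outside [0, n_classes)")
  structure(list(x = x, y = y, subject_id = as.integer(subject_id),
                 trial_id = as.integer(trial_id),
                 n_classes = as.integer(n_classes)),
            class = "SampleBatch")
}

#' @export
print.SampleBatch <- function(x, ...) {
  cat(sprintf("SampleBatch: %d samples x %d channels, %d classes\n",
              nrow(x$x), ncol(x$x), x$n_classes))
  invisible(x)
}

# Subset a SampleBatch by sample index.
batch_subset <- function(batch, idx) {
  sample_batch(batch$x[idx, , drop = FALSE], batch$y[idx],
               batch$subject_id[idx], batch$trial_id[idx], batch$n_classes)
}

#' Per-channel z-scoring with train-only statistics
#'
#' Computes per-channel mean and standard deviation on the training batch
#' only and applies the same affine transform to every supplied batch,
#' preventing information leakage from evaluation data. Standard deviations
#' are guarded by `eps`, so constant channels map to (approximately) zero.
#'
#' @param train the training `SampleBatch` (statistics source).
#' @param ... further `SampleBatch`es transformed with the train statistics.
#' @param eps guard added to standard deviations (default 1e-8).
#' @return list with `train`, `others` (list), and `stats`
#'   (list of `mean`, `sd` per channel).
#' @export
normalize_batches <- function(train, ..., eps = 1e-8) {
  stopifnot(inherits(train, "SampleBatch"), nrow(train$x) > 0)
  mu <- colMeans(train$x)
  # population sd, consistent across batch sizes
  sdv <- sqrt(colMeans(sweep(train$x, 2, mu)^2)) + eps
  apply_stats <- function(b) {
    b$x <- sweep(sweep(b$x, 2, mu), 2, sdv, "/")
    b
  }
  others <- lapply(list(...), apply_stats)
  list(train = apply_stats(train), others = others,
       stats = list(mean = mu, sd = sdv))
}

#' Encode raw labels as integer classes
#'
#' `seediv4` maps the four SEED-IV emotion names as neutral = 0, sad = 1,
#' fear = 2, happy = 3 (a fixed documented bijection; the numeric coding is
#' immaterial to the metrics). `dreamer_dim` maps self-assessment ratings
#' 1..5 to classes 0..4.
#'
#' @param raw_labels character vector (`seediv4`) or integer ratings
#'   (`dreamer_dim`).
#' @param mode `"seediv4"` or `"dreamer_dim"`.
#' @return integer class vector.
#' @export
encode_labels <- function(raw_labels, mode = c("seediv4", "dreamer_dim")) {
  mode <- match.arg(mode)
  if (mode == "seediv4") {
    map <- c(neutral = 0L, sad = 1L, fear = 2L, happy = 3L)
    out <- map[as.character(raw_labels)]
    if (any(is.na(out)))
      stop("unknown SEED-IV label; expected neutral/sad/fear/happy")
    unname(out)
  } else {
    r <- as.integer(raw_labels)
    if (any(is.na(r)) || any(r < 1L | r > 5L))
      stop("DREAMER ratings must lie in 1..5")
    r - 1L
  }
}

#' Subject-wise train/test split
#'
#' Holds out `n_test` randomly chosen subjects (seeded), assigning all their
#' samples to the test side — the subject-independent protocol that splits
#' 15 SEED-IV subjects 12/3 and 23 DREAMER subjects 18/5.
#'
#' @param subjects vector of distinct subject identifiers.
#' @param n_test number of held-out subjects (must be < number of subjects).
#' @param seed integer seed.
#' @return list with `train_subjects` and `test_subjects`.
#' @export
subject_split <- function(subjects, n_test, seed = 42) {
  subjects <- unique(subjects)
  if (n_test >= length(subjects))
    stop("n_test must be smaller than the number of subjects")
  if (n_test < 1) stop("n_test must be at least 1")
  test <- with_seed(seed, sample(subjects, n_test))
  list(train_subjects = setdiff(subjects, test), test_subjects = test)
}

#' k-fold assignment of sample indices
#'
#' Seeded shuffle followed by division into k near-equal folds (sizes differ
#' by at most one) that partition `1:n_samples`.
#'
#' @param n_samples number of samples.
#' @param k number of folds (default 10).
#' @param seed integer seed (default 42).
#' @return integer vector of length `n_samples` with fold ids in `1:k`.
#' @export
kfold_indices <- function(n_samples, k = 10, seed = 42) {
  if (n_samples < k) stop("need at least k samples for k folds")
  perm <- with_seed(seed, sample.int(n_samples))
  fold <- integer(n_samples)
  fold[perm] <- rep_len(seq_len(k), n_samples)
  fold
}
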