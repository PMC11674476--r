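#' Prepare model-ready samples from a trial set
#'
#' Extracts the centred fixed-length segment of every trial and slices it
#' into per-timepoint samples.
#'
#' @param trialset a `TrialSet`.
#' @param segment_length timepoints per extracted segment.
#' @param label_dim label dimension in `vad_triple` mode (1 valence,
#'   2 arousal, 3 dominance).
#' @return a `SampleBatch` with `n_trials * segment_length` samples.
#' @export
prepare_samples <- function(trialset, segment_length = 1000, label_dim = 1L) {
  segs <- trialset
  segs$trials <- lapply(trialset$trials, extract_middle_segment,
                        n = segment_length)
  slice_timepoint_samples(segs, label_dim = label_dim)
}

#' Evaluate a trained model on a batch
#'
#' Predicts by row-wise argmax over the softmax output (ties broken toward
#' the lowest class index) and scores the predictions with the full metric
#' suite.
#'
#' @param model a `DACBModel`.
#' @param batch a non-empty `SampleBatch`.
#' @param mcc_method multiclass MCC variant, see [mcc_score()].
#' @return a `MetricReport`.
#' @export
evaluate <- function(model, batch, mcc_method = "macro_ovr") {
  stopifnot(inherits(batch, "SampleBatch"), nrow(batch$x) > 0)
  pred <- predict_dacb(model, batch)
  metric_report(confusion_matrix(batch$y, pred, batch$n_classes), mcc_method)
}

#' Subject-wise single-split experiment
#'
#' Holds out `n_test_subjects` whole subjects (the 12/3 SEED-IV and 18/5
#' DREAMER protocol), z-scores channels with training-side statistics,
#' trains a fresh model and evaluates on the held-out subjects' samples.
#'
#' @param batch a `SampleBatch` with at least two subjects.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param n_test_subjects number of held-out subjects.
#' @param verbose print per-epoch loss.
#' @return a `RunResult`: list with `report`, `history`, `manifest`
#'   (seeds and subject assignment) and the trained `model`.
#' @export
run_single_split <- function(batch, model_cfg, train_cfg = train_config(),
                             n_test_subjects = 3, verbose = FALSE) {
  subjects <- unique(batch$subject_id)
  if (length(subjects) < 2) stop("need at least two subjects")
  sp <- subject_split(subjects, n_test_subjects, seed = train_cfg$seed)
  tr_idx <- which(batch$subject_id %in% sp$train_subjects)
  te_idx <- which(batch$subject_id %in% sp$test_subjects)
  nb <- normalize_batches(batch_subset(batch, tr_idx),
                          batch_subset(batch, te_idx))
  model <- dacb_model(model_cfg)
  model <- train_dacb(model, nb$train, train_cfg, verbose = verbose)
  list(report = evaluate(model, nb$others[[1]]),
       history = model$history,
       manifest = list(protocol = "subject_split", seed = train_cfg$seed,
                       train_subjects = sp$train_subjects,
                       test_subjects = sp$test_subjects),
       model = model)
}

# Fold assignment for a batch: over samples (the shuffled-timepoint reading
# of shuffle-everything protocols) or over whole trials (no adjacent-timepoint
# leakage across folds).
assign_folds <- function(batch, k, mode, seed) {
  if (mode == "sample_shuffled") {
    kfold_indices(nrow(batch$x), k = k, seed = seed)
  } else {
    ids <- unique(batch$trial_id)
    f <- kfold_indices(length(ids), k = k, seed = seed)
    f[match(batch$trial_id, ids)]
  }
}

#' 10-fold cross-validation experiment
#'
#' Runs `k` train/test cycles with a fresh, fold-seeded model per fold and
#' normalization statistics fit on each fold's training side; reports
#' per-fold metrics and their mean and standard deviation. Modes:
#' `sample_shuffled` shuffles individual timepoint samples into folds (the
#' shuffle-everything reading of the protocol, which lets adjacent timepoints of one trial
#' straddle folds), `trial_grouped` keeps whole trials together.
#'
#' @param batch a `SampleBatch`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; its seed drives fold assignment and
#'   the per-fold model seeds.
#' @param k number of folds (default 10).
#' @param mode `"sample_shuffled"` or `"trial_grouped"`.
#' @param folds optional precomputed fold vector (length `nrow(batch$x)`,
#'   values `1:k`), e.g. to share splits across ablation variants.
#' @param verbose print per-epoch loss.
#' @return a `RunResult`: list with `reports` (length k), `summary` (mean and
#'   sd per metric), `folds`, `manifest`.
#' @export
run_kfold <- function(batch, model_cfg, train_cfg = train_config(), k = 10,
                      mode = c("sample_shuffled", "trial_grouped"),
                      folds = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  folds <- folds %||% assign_folds(batch, k, mode, train_cfg$seed)
  reports <- vector("list", k)
  for (fold in seq_len(k)) {
    te_idx <- which(folds == fold)
    tr_idx <- which(folds != fold)
    nb <- normalize_batches(batch_subset(batch, tr_idx),
                            batch_subset(batch, te_idx))
    cfg <- model_cfg
    cfg$seed <- derive_seed(train_cfg$seed, fold)
    tcfg <- train_cfg
    tcfg$seed <- derive_seed(train_cfg$seed, 1000L + fold)
    model <- train_dacb(dacb_model(cfg), nb$train, tcfg, verbose = verbose)
    reports[[fold]] <- evaluate(model, nb$others[[1]])
  }
  vals <- sapply(reports, unlist)   # 5 x k
  list(reports = reports,
       summary = data.frame(metric = rownames(vals),
                            mean = rowMeans(vals),
                            sd = apply(vals, 1, sd)),
       folds = folds,
       manifest = list(protocol = "kfold", k = k, mode = mode,
                       seed = train_cfg$seed))
}

#' Ablation study: spatial-only, temporal-only and full model
#'
#' Runs the three variants through k-fold cross-validation on identical fold
#' assignments and returns a table of mean metrics per variant, mirroring
#' the standard single-branch ablation layout.
#'
#' @inheritParams run_kfold
#' @return list with `table` (data.frame: variant x mean metrics), `runs`
#'   (named list of `RunResult`s), `folds`.
#' @export
run_ablation <- function(batch, model_cfg, train_cfg = train_config(), k = 10,
                         mode = c("sample_shuffled", "trial_grouped"),
                         verbose = FALSE) {
  mode <- match.arg(mode)
  folds <- assign_folds(batch, k, mode, train_cfg$seed)
  variants <- c("block1_spatial_only", "block2_temporal_only", "full")
  runs <- lapply(variants, function(v) {
    cfg <- model_cfg
    cfg$variant <- v
    run_kfold(batch, cfg, train_cfg, k = k, mode = mode, folds = folds,
              verbose = verbose)
  })
  names(runs) <- variants
  tab <- do.call(rbind, lapply(variants, function(v) {
    s <- runs[[v]]$summary
    stats::setNames(data.frame(v, t(s$mean)), c("variant", s$metric))
  }))
  list(table = tab, runs = runs, folds = folds)
}

#' SE-unit and electrode contribution scores
#'
#' Exports two complementary attributions of a trained model: (1) the SE
#' excitation over the 64 convolution feature maps, batch-averaged both
#' before the sigmoid (`se_logits`, `W2 ELU(W1 z)`, which may be negative)
#' and after (`se_weights`, in (0,1)); and (2) per-electrode occlusion
#' scores — the drop in accuracy when each input channel is zeroed — one
#' value per electrode.
#'
#' @param model a trained `DACBModel` with a spatial branch.
#' @param batch a non-empty `SampleBatch`.
#' @param max_samples cap on rows used (subsampled deterministically) to
#'   bound the cost of the per-electrode passes.
#' @return list with `se_logits`, `se_weights` (length `conv_filters`) and
#'   `occlusion` (length `n_channels`).
#' @export
channel_contributions <- function(model, batch, max_samples = 20000L) {
  stopifnot(inherits(batch, "SampleBatch"), nrow(batch$x) > 0)
  if (!has_spatial(model$cfg))
    stop("channel contributions need a model with the spatial (SE) branch")
  n <- nrow(batch$x)
  if (n > max_samples)
    batch <- batch_subset(batch, with_seed(1L, sample.int(n, max_samples)))
  w <- branch_widths(model$cfg)
  sp <- spatial_forward(batch$x, model$params, model$cfg, w)
  e <- sp$cache$h %*% t(model$params$se_W2)   # pre-sigmoid excitation
  acc <- function(b) mean(predict_dacb(model, b) == b$y)
  base <- acc(batch)
  occl <- vapply(seq_len(model$cfg$n_channels), function(ch) {
    b <- batch
    b$x[, ch] <- 0
    base - acc(b)
  }, numeric(1))
  list(se_logits = colMeans(e), se_weights = colMeans(sp$cache$s),
       occlusion = occl, baseline_accuracy = base)
}
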