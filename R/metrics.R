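#' Confusion counts from labels and predictions
#'
#' Tallies an n_classes x n_classes matrix (rows = truth, columns =
#' prediction) and the derived per-class one-vs-rest TP/TN/FP/FN counts.
#'
#' @param y_true,y_pred integer class vectors in `0:(n_classes - 1)`.
#' @param n_classes number of classes.
#' @return a `ConfusionCounts` object: list with `matrix`, `tp`, `tn`, `fp`,
#'   `fn`, `total`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes))
    stop("labels outside [0, n_classes)")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(truth = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(y_true))
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  structure(list(matrix = m, tp = tp, tn = tn, fp = fp, fn = fn,
                 total = sum(m)), class = "ConfusionCounts")
}

# Build ConfusionCounts directly from a count matrix (rows = truth).
confusion_from_matrix <- function(m) {
  m <- as.matrix(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  structure(list(matrix = m, tp = tp, tn = tn, fp = fp, fn = fn,
                 total = sum(m)), class = "ConfusionCounts")
}

#' Classification accuracy
#'
#' Trace over total of the confusion matrix — the multiclass form of
#' (TP + TN) / (TP + TN + FP + FN), to which it reduces for two classes.
#'
#' @param cc a [confusion_matrix()] result.
#' @return proportion in `[0, 1]`.
#' @export
accuracy_score <- function(cc) {
  if (cc$total == 0) stop("empty confusion counts")
  sum(diag(cc$matrix)) / cc$total
}

#' Macro precision, recall and F1
#'
#' Per-class one-vs-rest precision TP/(TP+FP) and recall TP/(TP+FN) are
#' macro-averaged (classes with empty denominators contribute 0); F1 is the
#' harmonic mean of the macro aggregates, 0 when their sum is 0.
#'
#' @param cc a [confusion_matrix()] result.
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cc) {
  if (cc$total == 0) stop("empty confusion counts")
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- mean(safe_div(cc$tp, cc$tp + cc$fp))
  rec <- mean(safe_div(cc$tp, cc$tp + cc$fn))
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1)
}

# Binary MCC from one-vs-rest counts; 0 whenever a denominator factor is 0.
mcc_binary <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Matthews correlation coefficient
#'
#' For two classes this is the textbook formula
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0 when
#' any denominator factor vanishes. The default multiclass extension
#' (`"macro_ovr"`) macro-averages the per-class one-vs-rest binary values;
#' `"multiclass"` selects the matrix-correlation generalization instead.
#'
#' @param cc a [confusion_matrix()] result.
#' @param method `"macro_ovr"` or `"multiclass"`.
#' @return value in `[-1, 1]`.
#' @export
mcc_score <- function(cc, method = c("macro_ovr", "multiclass")) {
  method <- match.arg(method)
  if (method == "macro_ovr") {
    mean(vapply(seq_along(cc$tp), function(k)
      mcc_binary(cc$tp[k], cc$tn[k], cc$fp[k], cc$fn[k]), numeric(1)))
  } else {
    m <- cc$matrix
    n <- sum(m); tr <- sum(diag(m))
    rs <- rowSums(m); csums <- colSums(m)
    num <- tr * n - sum(rs * csums)
    den <- sqrt(n^2 - sum(csums^2)) * sqrt(n^2 - sum(rs^2))
    if (den == 0) 0 else num / den
  }
}

#' Full metric report for one evaluation
#'
#' @param cc a [confusion_matrix()] result.
#' @param mcc_method multiclass MCC variant, see [mcc_score()].
#' @return a `MetricReport`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `mcc`.
#' @export
metric_report <- function(cc, mcc_method = "macro_ovr") {
  prf <- precision_recall_f1(cc)
  structure(list(accuracy = accuracy_score(cc), precision = prf$precision,
                 recall = prf$recall, f1 = prf$f1,
                 mcc = mcc_score(cc, mcc_method)),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f  precision %.4f  recall %.4f  ",
                     "f1 %.4f  mcc %.4f\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Serialize metric reports
#'
#' @param reports a `MetricReport` or list of them.
#' @param path output file; `.json` writes a JSON array, anything else a CSV
#'   with one row per report.
#' @return `path`, invisibly.
#' @export
write_metric_reports <- function(reports, path) {
  if (inherits(reports, "MetricReport")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, mcc = r$mcc)))
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  else
    write.csv(df, path, row.names = FALSE)
  invisible(path)
}
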