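# Independent counting oracle for the confusion tally.
oracle_confusion <- function(y_true, y_pred, k) {
  m <- matrix(0L, k, k)
  for (i in seq_along(y_true))
    for (a in 0:(k - 1)) for (b in 0:(k - 1))
      if (y_true[i] == a && y_pred[i] == b) m[a + 1, b + 1] <- m[a + 1, b + 1] + 1L
  m
}

# Binary confusion counts arranged so class 1 is "positive".
binary_cc <- function(tp, tn, fp, fn) {
  confusion_matrix(
    y_true = c(rep(1L, tp + fn), rep(0L, tn + fp)),
    y_pred = c(rep(1L, tp), rep(0L, fn), rep(0L, tn), rep(1L, fp)),
    n_classes = 2)
}

test_that("confusion tallies match a brute-force counting oracle", {
  y <- c(0L, 1L, 2L, 1L)
  cc <- confusion_matrix(y, y, 3)
  expect_true(all(cc$matrix[upper.tri(cc$matrix)] == 0))
  expect_true(all(cc$matrix[lower.tri(cc$matrix)] == 0))
  expect_equal(cc$total, 4)
  set.seed(14)
  for (i in 1:20) {
    yt <- sample(0:2, 50, replace = TRUE)
    yp <- sample(0:2, 50, replace = TRUE)
    cc <- confusion_matrix(yt, yp, 3)
    expect_equal(unname(cc$matrix), oracle_confusion(yt, yp, 3))
    expect_equal(cc$total, 50)
    expect_equal(unname(cc$tp + cc$fn), unname(rowSums(cc$matrix)))
    expect_equal(unname(cc$tp + cc$tn + cc$fp + cc$fn), rep(50, 3))
  }
  expect_error(confusion_matrix(0:2, 0:1, 3), "length")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "outside")
})

test_that("accuracy, precision, recall and F1 reproduce hand cases", {
  cc <- binary_cc(tp = 3, tn = 5, fp = 1, fn = 1)
  expect_equal(accuracy_score(cc), 0.8)
  # TP=3, FP=1, FN=1 with mirrored negative-class counts: the binary
  # formulas give 0.75 for each of precision, recall and harmonic-mean F1,
  # and the macro average agrees because both classes score alike
  prf <- precision_recall_f1(binary_cc(tp = 3, tn = 3, fp = 1, fn = 1))
  expect_equal(prf$precision, 0.75)
  expect_equal(prf$recall, 0.75)
  expect_equal(prf$f1, 0.75)
  expect_equal(3 / (3 + 1), 0.75)   # Eq. check: TP/(TP+FP) on the positive class

  perfect <- confusion_matrix(rep(0:3, 5), rep(0:3, 5), 4)
  rep_perfect <- metric_report(perfect)
  expect_equal(unlist(rep_perfect), c(accuracy = 1, precision = 1,
                                      recall = 1, f1 = 1, mcc = 1))
})

test_that("macro precision/recall/F1 match a per-class loop oracle", {
  set.seed(15)
  for (i in 1:20) {
    yt <- sample(0:3, 80, replace = TRUE)
    yp <- sample(0:3, 80, replace = TRUE)
    cc <- confusion_matrix(yt, yp, 4)
    precs <- recs <- numeric(4)
    for (cl in 0:3) {
      tp <- sum(yt == cl & yp == cl)
      fp <- sum(yt != cl & yp == cl)
      fn <- sum(yt == cl & yp != cl)
      precs[cl + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
      recs[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    }
    prf <- precision_recall_f1(cc)
    expect_equal(prf$precision, mean(precs))
    expect_equal(prf$recall, mean(recs))
    pm <- mean(precs); rm <- mean(recs)
    expect_equal(prf$f1, if (pm + rm > 0) 2 * pm * rm / (pm + rm) else 0)
    expect_equal(accuracy_score(cc), mean(yt == yp))
  }
})

test_that("MCC attains its extremes and matches the printed formula", {
  expect_equal(mcc_score(binary_cc(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  expect_equal(mcc_score(binary_cc(tp = 0, tn = 0, fp = 5, fn = 5)), -1)
  set.seed(16)
  for (i in 1:20) {
    tp <- sample(0:10, 1); tn <- sample(0:10, 1)
    fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fn == 0 || tn + fp == 0) next   # need both classes present
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    expected <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    expect_equal(mcc_score(binary_cc(tp, tn, fp, fn)), expected)
  }
  # multiclass macro one-vs-rest vs per-class formula oracle
  for (i in 1:20) {
    yt <- sample(0:3, 60, replace = TRUE)
    yp <- sample(0:3, 60, replace = TRUE)
    cc <- confusion_matrix(yt, yp, 4)
    vals <- numeric(4)
    for (cl in 0:3) {
      tp <- sum(yt == cl & yp == cl); fp <- sum(yt != cl & yp == cl)
      fn <- sum(yt == cl & yp != cl); tn <- 60 - tp - fp - fn
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      vals[cl + 1] <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    }
    expect_equal(mcc_score(cc), mean(vals))
    expect_gte(mcc_score(cc), -1); expect_lte(mcc_score(cc), 1)
  }
  # matrix-correlation variant against its closed form
  m <- matrix(c(10, 2, 1, 3, 12, 2, 0, 1, 9), 3, byrow = TRUE)
  cc <- dacb:::confusion_from_matrix(m)
  n <- sum(m); tr <- sum(diag(m)); rs <- rowSums(m); cs <- colSums(m)
  expect_equal(mcc_score(cc, method = "multiclass"),
               (tr * n - sum(rs * cs)) /
                 (sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))))
})

test_that("metrics are invariant under relabeling and never NaN", {
  set.seed(17)
  yt <- sample(0:3, 100, replace = TRUE)
  yp <- sample(0:3, 100, replace = TRUE)
  r1 <- unlist(metric_report(confusion_matrix(yt, yp, 4)))
  perm <- sample(0:3)
  r2 <- unlist(metric_report(confusion_matrix(perm[yt + 1], perm[yp + 1], 4)))
  expect_equal(r1, r2)

  # degenerate predictor: zero denominators contribute 0, never NaN
  rep0 <- metric_report(confusion_matrix(yt, rep(0L, 100), 4))
  expect_false(any(is.na(unlist(rep0))))
})

test_that("MCC of label-shuffled balanced predictions is near zero", {
  set.seed(18)
  y <- rep(0:3, each = 2500)
  pred <- sample(y)
  cc <- confusion_matrix(y, pred, 4)
  expect_lt(abs(mcc_score(cc)), 0.05)
})

test_that("metric reports serialize to CSV and JSON", {
  cc <- binary_cc(3, 5, 1, 1)
  rep1 <- metric_report(cc)
  csv <- file.path(tempdir(), "mr.csv"); js <- file.path(tempdir(), "mr.json")
  write_metric_reports(rep1, csv)
  write_metric_reports(list(rep1, rep1), js)
  expect_equal(read.csv(csv)$accuracy, 0.8)
  expect_length(jsonlite::read_json(js), 2)
  unlink(c(csv, js))
})
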