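# independent brute-force oracles used throughout this file
naive_f1 <- function(y_true, y_pred, K, average) {
  f1s <- supp <- numeric(K)
  for (k in seq_len(K)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    supp[k] <- sum(y_true == k)
  }
  switch(average, none = f1s, macro = mean(f1s),
         weighted = if (sum(supp) == 0) 0 else sum(f1s * supp) / sum(supp))
}

naive_fmax <- function(y, p) { # exhaustive sweep over candidate thresholds
  cand <- sort(unique(c(0, 1, p)))
  best <- -1; bt <- NA
  for (t in cand) {
    pred <- p >= t
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    if (f > best + 1e-12) { best <- f; bt <- t }
  }
  c(threshold = bt, fmax = best)
}

concordance_auc <- function(y, s) { # Mann-Whitney pairwise statistic
  pos <- s[y]; neg <- s[!y]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

test_that("decisions are argmax with lowest-index tie-breaking", {
  probs <- rbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0.0), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(max.col(probs, ties.method = "first"), c(2, 1, 1))
  m <- build_model(tiny_spec(K = 3), seed = 8)
  x <- array(rnorm(10 * 2 * 32), c(10, 2, 32))
  pr <- predict_proba(m, x)
  expect_equal(rowSums(pr$probs), rep(1, 10), tolerance = 1e-6)
  expect_equal(pr$decision, max.col(pr$probs, ties.method = "first"))
  expect_error(predict_proba(m, array(0, c(2, 3, 32))), class = "ShapeError")
})

test_that("confusion matrix counts true-by-predicted", {
  expect_equal(confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2),
               matrix(c(1L, 0L, 1L, 1L), 2))
  perfect <- confusion_matrix(c(1, 2, 2, 3), c(1, 2, 2, 3), 3)
  expect_equal(diag(perfect), c(1L, 2L, 1L))
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))
  expect_equal(confusion_matrix(integer(0), integer(0), 2), matrix(0L, 2, 2))
  expect_error(confusion_matrix(c(1, 4), c(1, 1), 3), class = "LabelError")
})

test_that("F1 worked example and support-0 rule", {
  y <- c(1, 1, 2, 2); p <- c(1, 2, 2, 2)
  expect_equal(f1_score(y, p, 2, "none"), c(2 / 3, 4 / 5))
  expect_equal(f1_score(y, p, 2, "macro"), mean(c(2 / 3, 4 / 5)))
  expect_equal(f1_score(y, p, 2, "weighted"), (2 / 3 + 4 / 5) / 2)
  expect_equal(f1_score(y, y, 2, "weighted"), 1)
  # class 3 absent from truth and prediction: F1 0, excluded from weighting
  expect_equal(f1_score(y, p, 3, "none")[3], 0)
  expect_equal(f1_score(y, p, 3, "weighted"), (2 / 3 + 4 / 5) / 2)
})

test_that("Fmax worked examples", {
  r <- fmax_thresholds(c(1, 1, 2, 2), cbind(c(0.9, 0.8, 0.3, 0.1),
                                            c(0.1, 0.2, 0.7, 0.9)))
  expect_equal(r$fmax[1], 1.0)
  expect_equal(r$threshold[1], 0.8) # lowest unique prob achieving F1 = 1
  # all-positive class: threshold 0 predicts everything, F1 = 1
  r2 <- fmax_thresholds(rep(1, 4), cbind(c(0.5, 0.1, 0.9, 0.2)))
  expect_equal(r2$threshold[1], 0)
  expect_equal(r2$fmax[1], 1.0)
  # class with zero positives is flagged
  r3 <- fmax_thresholds(rep(1, 4), cbind(runif(4), runif(4)))
  expect_true(r3$flagged[2])
  expect_equal(r3$threshold[2], 1)
  expect_equal(r3$fmax[2], 0)
})

test_that("f1, fmax and ROC area equal brute force on 200 random instances", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5:30, 1); K <- sample(2:4, 1)
    y <- sample(K, n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(K, n, replace = TRUE)
    pred <- sample(K, n, replace = TRUE)
    for (avg in c("none", "macro", "weighted"))
      expect_equal(f1_score(y, pred, K, avg), naive_f1(y, pred, K, avg))
    probs <- matrix(runif(n * K), n); probs <- probs / rowSums(probs)
    fm <- fmax_thresholds(y, probs)
    for (k in seq_len(K)) {
      if (fm$flagged[k]) next
      oracle <- naive_fmax(y == k, probs[, k])
      expect_equal(fm$fmax[k], unname(oracle["fmax"]))
      expect_equal(fm$threshold[k], unname(oracle["threshold"]))
    }
    pos <- y == sample(unique(y), 1)
    if (any(pos) && !all(pos)) {
      rc <- roc_curve(pos, probs[, 1])
      expect_equal(rc$auc, concordance_auc(pos, probs[, 1]), tolerance = 1e-12)
    }
  }
})

test_that("ROC curves have the standard endpoints and shapes", {
  perfect <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  flat <- roc_curve(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)
  expect_equal(range(flat$fpr), c(0, 1))
  expect_true(all(diff(flat$tpr) >= 0) && all(diff(flat$fpr) >= 0))
  expect_error(roc_curve(rep(TRUE, 5), runif(5)), class = "DegenerateROC")
})

test_that("ROC area agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  s <- runif(40)
  ours <- roc_curve(y, s)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("calibration scores follow the documented conventions", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  cal <- calibration(c(1, 2, 3, 1), onehot)
  expect_equal(cal$brier, 0)
  expect_equal(cal$ece, 0)
  # uniform two-class predictions on balanced truth: Brier 0.5 (summed squares)
  half <- matrix(0.5, 4, 2)
  cal2 <- calibration(c(1, 1, 2, 2), half)
  expect_equal(cal2$brier, 0.5)
  # constant confidence 0.8 with accuracy 0.8 is perfectly calibrated
  probs <- matrix(c(0.8, 0.2), 5, 2, byrow = TRUE)
  y <- c(1, 1, 1, 1, 2) # predicted class 1, correct 4/5
  expect_equal(calibration(y, probs)$ece, 0)
})

test_that("bootstrap intervals are deterministic and cover the point estimate", {
  y <- c(1, 1, 2, 2); p <- c(1, 2, 2, 2)
  wf1 <- function(yt, yp) f1_score(yt, yp, 2, "weighted")
  ci <- bootstrap_ci(wf1, y, p, n_resamples = 200, seed = 5)
  ci2 <- bootstrap_ci(wf1, y, p, n_resamples = 200, seed = 5)
  expect_identical(ci, ci2)
  point <- wf1(y, p) # 0.733...
  expect_lte(ci[1], point); expect_gte(ci[2], point)
  # constant metric collapses the interval
  cperf <- bootstrap_ci(function(yt, yp) mean(yt == yp), y, y,
                        n_resamples = 50, seed = 1)
  expect_equal(cperf, c(1, 1))
})

test_that("aggregate metrics are record-order invariant and bounded", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 25; K <- 3
    y <- sample(K, n, replace = TRUE)
    pred <- sample(K, n, replace = TRUE)
    perm <- sample(n)
    for (avg in c("macro", "weighted"))
      expect_equal(f1_score(y, pred, K, avg), f1_score(y[perm], pred[perm], K, avg))
    f1s <- f1_score(y, pred, K, "none")
    w <- f1_score(y, pred, K, "weighted")
    present <- rowSums(confusion_matrix(y, pred, K)) > 0
    expect_gte(w, min(f1s[present]) - 1e-12)
    expect_lte(w, max(f1s[present]) + 1e-12)
  }
})

test_that("the full evaluation report assembles and serializes", {
  set.seed(9)
  n <- 30; K <- 3
  y <- sample(K, n, replace = TRUE)
  probs <- matrix(runif(n * K), n); probs <- probs / rowSums(probs)
  rep <- evaluate_predictions(y, probs, classes = c("a", "b", "c"),
                              bootstrap = TRUE, n_resamples = 50, seed = 2)
  expect_equal(sum(rep$confusion), n)
  expect_true(all(rep$per_class$f1 >= 0 & rep$per_class$f1 <= 1))
  expect_length(rep$ci_weighted_f1, 2)
  d <- withr::local_tempdir()
  write_eval_report(rep, file.path(d, "eval"))
  expect_true(file.exists(file.path(d, "eval.json")))
  expect_true(file.exists(file.path(d, "eval_confusion.csv")))
})
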