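# ---------------------------------------------------------------------------
# Prediction and evaluation: argmax decision rule, confusion matrix, the F1
# family, per-class ROC, Fmax threshold suggestion, calibration (Brier +
# top-label ECE) and bootstrap confidence intervals.
# ---------------------------------------------------------------------------

#' Predict class probabilities and decisions
#'
#' Applies the model in inference mode, converts logits to softmax
#' probabilities and decides by the highest probability; ties resolve to the
#' lowest class index.
#'
#' @param model an `ecg_model`.
#' @param x input array `[n x channels x samples]` (or a single
#'   `[channels x samples]` matrix), already preprocessed to the model's
#'   input shape.
#' @param batch_size forward-pass batch size.
#' @return list with `probs` (`[n x K]`, rows sum to 1), `decision`
#'   (1-based integer class indices) and `logits`.
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3L ||
      dim(x)[2] != model$spec$in_channels || dim(x)[3] != model$spec$n_samples)
    ecg_stop("ShapeError", "expected input [n x %d x %d], got [%s]",
             model$spec$in_channels, model$spec$n_samples,
             paste(dim(x), collapse = " x "))
  n <- dim(x)[1]
  K <- model$spec$n_classes
  logits <- matrix(NA_real_, n, K)
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- (((b - 1) * batch_size + 1):min(b * batch_size, n))
    logits[idx, ] <- model_forward(model, x[idx, , , drop = FALSE],
                                   training = FALSE)$logits
  }
  probs <- softmax_rows(logits)
  list(probs = probs, decision = max.col(probs, ties.method = "first"),
       logits = logits)
}

#' Confusion matrix
#'
#' @param y_true,y_pred 1-based integer class indices.
#' @param K number of classes.
#' @return `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) && (min(y_true, y_pred) < 1 || max(y_true, y_pred) > K))
    ecg_stop("LabelError", "labels outside [1, %d]", K)
  m <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  m
}

#' F1 scores
#'
#' Per-class F1 = 2PR/(P+R) with the 0/0 case defined as 0. `macro` averages
#' all classes equally; `weighted` weights by true-class support, excluding
#' support-0 classes.
#'
#' @inheritParams confusion_matrix
#' @param average `"weighted"`, `"macro"` or `"none"` (per-class vector).
#' @return a scalar, or a length-`K` vector for `average = "none"`.
#' @export
f1_score <- function(y_true, y_pred, K, average = c("weighted", "macro", "none")) {
  average <- match.arg(average)
  cm <- confusion_matrix(y_true, y_pred, K)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  switch(average,
         none = as.numeric(f1),
         macro = mean(f1),
         weighted = {
           support <- rowSums(cm)
           if (sum(support) == 0) 0 else sum(f1 * support) / sum(support)
         })
}

#' Per-class Fmax thresholds
#'
#' For each class (one vs rest), sweeps the decision threshold over the
#' class's unique predicted probabilities plus 0 and 1 (decision rule
#' `prob >= threshold`) and returns the threshold maximizing binary F1; ties
#' resolve to the lowest threshold. Classes without positives are flagged and
#' given threshold 1 and Fmax 0.
#'
#' @param y_true 1-based integer class indices.
#' @param probs probability matrix `[n x K]`.
#' @return data frame with `class`, `threshold`, `fmax`, `flagged`.
#' @export
fmax_thresholds <- function(y_true, probs) {
  K <- ncol(probs)
  res <- data.frame(class = seq_len(K), threshold = NA_real_,
                    fmax = NA_real_, flagged = FALSE)
  for (k in seq_len(K)) {
    pos <- y_true == k
    if (!any(pos)) {
      res$threshold[k] <- 1; res$fmax[k] <- 0; res$flagged[k] <- TRUE
      next
    }
    cand <- sort(unique(c(0, 1, probs[, k])))
    best_f <- -1; best_t <- NA_real_
    for (t in cand) {
      pred <- probs[, k] >= t
      tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
      f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
      if (f > best_f + 1e-12) { best_f <- f; best_t <- t }
    }
    res$threshold[k] <- best_t; res$fmax[k] <- best_f
  }
  res
}

#' Per-class ROC curve
#'
#' Standard threshold sweep over one-vs-rest scores; the curve starts at
#' (0, 0), ends at (1, 1) and is monotone non-decreasing. The area is the
#' trapezoidal integral (equal to the Mann-Whitney concordance).
#'
#' @param y_true logical or 0/1 vector of positives.
#' @param scores numeric scores, higher = more positive.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  y <- as.logical(y_true)
  if (all(y) || !any(y))
    ecg_stop("DegenerateROC", "ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  keep <- c(diff(ss) != 0, TRUE)       # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, ss[keep]), auc = auc)
}

#' Calibration scores
#'
#' Brier score: mean over records of the summed squared error between the
#' one-hot truth and the probability row. Top-label expected calibration
#' error: records are binned into 10 equal-width bins of predicted-class
#' confidence; ECE is the support-weighted mean absolute gap between bin
#' accuracy and bin confidence.
#'
#' @param y_true 1-based integer class indices.
#' @param probs probability matrix `[n x K]`, rows summing to 1.
#' @param n_bins number of confidence bins (default 10).
#' @return list with `brier` and `ece`.
#' @export
calibration <- function(y_true, probs, n_bins = 10L) {
  n <- nrow(probs); K <- ncol(probs)
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), y_true)] <- 1
  brier <- mean(rowSums((probs - onehot)^2))
  conf <- apply(probs, 1, max)
  pred <- max.col(probs, ties.method = "first")
  correct <- pred == y_true
  bins <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  ece <- 0
  for (b in seq_len(n_bins)) {
    in_b <- bins == b
    if (!any(in_b)) next
    ece <- ece + sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  list(brier = brier, ece = ece)
}

#' Bootstrap percentile confidence interval for a metric
#'
#' Resamples records with replacement `n_resamples` times and returns the
#' 2.5/97.5 percentile interval of the metric. Resamples on which the metric
#' is undefined (error or non-finite) are redrawn up to 10 times, then
#' skipped with a warning. Deterministic given `seed`.
#'
#' @param metric function of `(y_true, y_hat)` returning a scalar, where
#'   `y_hat` is whatever `y_pred_or_probs` holds per record.
#' @param y_true 1-based integer class indices.
#' @param y_pred_or_probs vector of decisions or matrix of probabilities.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return numeric `c(lower, upper)` 95% interval.
#' @export
bootstrap_ci <- function(metric, y_true, y_pred_or_probs, n_resamples = 1000L,
                         seed = 42L) {
  n <- length(y_true)
  if (n < 2) ecg_stop("EmptyDataset", "bootstrap needs n >= 2")
  take <- function(obj, idx) if (is.matrix(obj)) obj[idx, , drop = FALSE] else obj[idx]
  vals <- rep(NA_real_, n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(metric(y_true[idx], take(y_pred_or_probs, idx)),
                      error = function(e) NA_real_)
        if (is.finite(v)) { vals[r] <- v; break }
      }
    }
  })
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " resamples had an undefined metric and were skipped")
    vals <- vals[!is.na(vals)]
  }
  as.numeric(stats::quantile(vals, c(0.025, 0.975), type = 7, names = FALSE))
}

#' Full evaluation report
#'
#' @param y_true 1-based integer class indices.
#' @param probs probability matrix `[n x K]`.
#' @param classes optional class names.
#' @param bootstrap if `TRUE`, adds 95% bootstrap CIs for the aggregate
#'   scores.
#' @param n_resamples,seed bootstrap settings.
#' @return an `eval_report`: confusion matrix, per-class precision/recall/F1,
#'   weighted/macro F1, accuracy, Brier, top-label ECE, suggested Fmax
#'   thresholds and optional CIs.
#' @export
evaluate_predictions <- function(y_true, probs, classes = NULL,
                                 bootstrap = FALSE, n_resamples = 1000L,
                                 seed = 42L) {
  K <- ncol(probs)
  if (is.null(classes)) classes <- as.character(seq_len(K))
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(y_true, pred, K)
  dimnames(cm) <- list(true = classes, pred = classes)
  cal <- calibration(y_true, probs)
  prec <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), 0)
  rep <- list(
    confusion = cm,
    per_class = data.frame(class = classes, support = rowSums(cm),
                           precision = as.numeric(prec), recall = as.numeric(rec),
                           f1 = f1_score(y_true, pred, K, "none")),
    weighted_f1 = f1_score(y_true, pred, K, "weighted"),
    macro_f1 = f1_score(y_true, pred, K, "macro"),
    accuracy = mean(pred == y_true),
    brier = cal$brier, ece = cal$ece,
    fmax = cbind(fmax_thresholds(y_true, probs)[-1],
                 class = classes, stringsAsFactors = FALSE)
  )
  if (bootstrap) {
    rep$ci_weighted_f1 <- bootstrap_ci(function(y, p) f1_score(y, p, K, "weighted"),
                                       y_true, pred, n_resamples, seed)
    rep$ci_macro_f1 <- bootstrap_ci(function(y, p) f1_score(y, p, K, "macro"),
                                    y_true, pred, n_resamples, derive_seed(seed, "macro"))
    rep$ci_accuracy <- bootstrap_ci(function(y, p) mean(y == p),
                                    y_true, pred, n_resamples, derive_seed(seed, "acc"))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, weighted F1 %.3f, macro F1 %.3f, accuracy %.3f\n",
              sum(x$confusion), x$weighted_f1, x$macro_f1, x$accuracy))
  cat(sprintf("  Brier %.4f, top-label ECE %.4f\n", x$brier, x$ece))
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits `<stem>.json` plus CSVs of the confusion matrix and per-class table.
#'
#' @param report an `eval_report`.
#' @param stem output path without extension.
#' @return invisibly, the JSON path.
#' @export
write_eval_report <- function(report, stem) {
  out <- unclass(report)
  out$confusion_classes <- colnames(report$confusion)
  out$confusion <- unname(out$confusion) # nested numeric arrays in JSON
  jsonlite::write_json(out, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  utils::write.csv(report$confusion, paste0(stem, "_confusion.csv"))
  utils::write.csv(report$per_class, paste0(stem, "_per_class.csv"),
                   row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
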