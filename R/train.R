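# ---------------------------------------------------------------------------
# Fixed one-command training / fine-tuning protocol.
#
# Defaults: AdamW, initial learning rate picked by an exponential range test,
# per-epoch exponential decay (gamma = 0.9), batch size 32, stratified 80/20
# train/evaluation split, at most 50 epochs, checkpointing on the lowest
# class-weighted validation cross-entropy, early stopping (patience 10).
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param optimizer `"adamw"` (default), `"adam"` or `"sgd"`.
#' @param initial_lr initial learning rate; `NULL` (default) runs the
#'   learning-rate finder ([find_lr()]) first.
#' @param lr_decay_gamma per-epoch exponential decay factor (default 0.9).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs maximum number of epochs (default 50).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 10).
#' @param split_fraction training fraction of the stratified split
#'   (default 0.8).
#' @param strategy `"full"` trains every layer; `"head"` trains only the
#'   classification head (backbone frozen).
#' @param weight_decay decoupled weight decay for AdamW (default 0.01).
#' @param momentum SGD momentum (default 0.9; ignored by Adam/AdamW).
#' @param lr_finder_iters iterations of the learning-rate range test.
#' @param seed master seed; split, initialization and shuffling seeds are
#'   derived from it.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = c("adamw", "adam", "sgd"), initial_lr = NULL,
                         lr_decay_gamma = 0.9, batch_size = 32L, max_epochs = 50L,
                         early_stop_patience = 10L, split_fraction = 0.8,
                         strategy = c("full", "head"), weight_decay = 0.01,
                         momentum = 0.9, lr_finder_iters = 100L, seed = 42L) {
  optimizer <- match.arg(optimizer)
  strategy <- match.arg(strategy)
  stopifnot(split_fraction > 0, split_fraction < 1, max_epochs >= 1,
            lr_decay_gamma > 0, lr_decay_gamma <= 1)
  structure(list(optimizer = optimizer, initial_lr = initial_lr,
                 lr_decay_gamma = lr_decay_gamma, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fraction = split_fraction, strategy = strategy,
                 weight_decay = weight_decay, momentum = momentum,
                 lr_finder_iters = as.integer(lr_finder_iters),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/evaluation split
#'
#' Per class `c` with `n_c` members, the training set receives
#' `round(fraction * n_c)` records (clamped to `[1, n_c - 1]`); the remainder
#' forms the evaluation set. Deterministic given `seed`.
#'
#' @param labels per-record class labels (factor or character).
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `eval`.
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 42L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2))
    ecg_stop("StratificationError",
             "every class needs >= 2 records; offending: %s",
             paste(names(counts)[counts < 2], collapse = ", "))
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, eval = setdiff(seq_along(labels), train))
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` for `N` records over `K` classes; the per-record
#' average of the weights is exactly 1. Used in the class-weighted
#' cross-entropy objective for both training and validation.
#'
#' @param labels per-record class labels (factor preserving the vocabulary).
#' @return named numeric weight vector, one entry per class.
#' @export
class_weights <- function(labels) {
  labels <- as.factor(labels)
  if (length(labels) == 0) ecg_stop("EmptyDataset", "no labels supplied")
  counts <- table(labels)
  K <- length(counts)
  w <- length(labels) / (K * as.numeric(counts))
  stats::setNames(w, names(counts))
}

# -- weighted softmax cross-entropy -----------------------------------------

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# y: 1-based class indices; w: per-class weights. Weighted mean of negative
# log-likelihoods; gradient normalized by the summed weights of the batch.
weighted_ce <- function(logits, y, w) {
  p <- softmax_rows(logits)
  wy <- w[y]
  eps <- 1e-12
  loss <- -sum(wy * log(p[cbind(seq_along(y), y)] + eps)) / sum(wy)
  onehot <- matrix(0, nrow(logits), ncol(logits))
  onehot[cbind(seq_along(y), y)] <- 1
  grad <- (p - onehot) * wy / sum(wy)
  list(loss = loss, grad = grad)
}

# -- optimizers --------------------------------------------------------------

opt_new <- function(kind, params, trainable) {
  st <- list()
  for (id in names(params)) {
    if (!isTRUE(trainable[[id]])) next
    st[[id]] <- lapply(params[[id]], function(v) {
      if (is.null(v)) NULL
      else list(m = array(0, dim(v) %||% length(v)), v = array(0, dim(v) %||% length(v)))
    })
  }
  list(kind = kind, state = st, t = 0L)
}

opt_step <- function(opt, params, grads, lr, config) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      if (is.null(g)) next
      p <- params[[id]][[nm]]
      if (opt$kind == "sgd") {
        s <- opt$state[[id]][[nm]]
        s$m <- config$momentum * s$m + g
        p <- p - lr * s$m
        opt$state[[id]][[nm]] <- s
      } else {
        s <- opt$state[[id]][[nm]]
        s$m <- b1 * s$m + (1 - b1) * g
        s$v <- b2 * s$v + (1 - b2) * g * g
        upd <- (s$m / bc1) / (sqrt(s$v / bc2) + eps)
        if (opt$kind == "adamw") p <- p - lr * (upd + config$weight_decay * p)
        else p <- p - lr * upd
        opt$state[[id]][[nm]] <- s
      }
      params[[id]][[nm]] <- p
    }
  }
  list(opt = opt, params = params)
}

# -- learning-rate range test ------------------------------------------------

#' Learning-rate finder
#'
#' Exponential learning-rate sweep (default 100 iterations from 1e-7 to 1)
#' recording an exponentially smoothed training loss (factor 0.05). Returns
#' the rate at the smoothed-loss minimum divided by 10, clamped to
#' `[1e-6, 1e-1]`. The sweep aborts once the loss exceeds four times its best
#' value. Model and optimizer state are restored afterwards.
#'
#' @param model an `ecg_model`.
#' @param x training inputs, array `[n x channels x samples]`.
#' @param y 1-based integer class indices.
#' @param w per-class weight vector.
#' @param config a [train_config()].
#' @return the chosen initial learning rate. Falls back to 1e-3 with a
#'   warning if no finite loss was observed.
#' @export
find_lr <- function(model, x, y, w, config = train_config()) {
  n <- dim(x)[1]
  if (n < 1) ecg_stop("EmptyDataset", "need at least one record")
  saved_params <- clone_params(model$params)
  saved_state <- model$state
  iters <- config$lr_finder_iters
  lrs <- 10^seq(log10(1e-7), log10(1), length.out = iters)
  opt <- opt_new(config$optimizer, model$params, model$trainable)
  bs <- min(config$batch_size, n)
  smooth <- NA_real_; best <- Inf
  rec <- rep(NA_real_, iters)
  with_seed(derive_seed(config$seed, "lrfinder"), {
    order <- sample(n)
    pos <- 1L
    for (i in seq_len(iters)) {
      if (pos + bs - 1L > n) { order <- sample(n); pos <- 1L }
      idx <- order[pos:(pos + bs - 1L)]; pos <- pos + bs
      fw <- nn_train_batch(model, x[idx, , , drop = FALSE], y[idx], w)
      model <- fw$model
      if (!is.finite(fw$loss)) break
      smooth <- if (is.na(smooth)) fw$loss else 0.05 * fw$loss + 0.95 * smooth
      rec[i] <- smooth
      if (smooth < best) best <- smooth
      if (smooth > 4 * best && i > 10) break
      st <- opt_step(opt, model$params, fw$grads, lrs[i], config)
      opt <- st$opt; model$params <- st$params
    }
  })
  model$params <- saved_params
  model$state <- saved_state
  if (all(is.na(rec))) {
    warning("learning-rate finder saw no finite loss; falling back to 1e-3")
    return(1e-3)
  }
  lr <- lrs[which.min(rec)] / 10
  min(max(lr, 1e-6), 1e-1)
}

# -- the training loop -------------------------------------------------------

#' Train or fine-tune a classifier
#'
#' Runs the fixed protocol: stratified 80/20 split, optional learning-rate
#' finder, configured optimizer with per-epoch exponential decay, per-epoch
#' class-weighted cross-entropy on the evaluation split, checkpointing of the
#' best epoch and early stopping. The returned model carries the checkpointed
#' parameters.
#'
#' @param model an `ecg_model` whose head width matches the dataset's class
#'   count (use [adapt_head()] first otherwise).
#' @param dataset a `labeled_dataset` (see [generate_dataset()] or
#'   [as_labeled_dataset()]) whose records are already shaped to the model
#'   input.
#' @param config a [train_config()].
#' @return list with elements `model` (best checkpoint) and `report`
#'   (a `train_report`).
#' @export
fit <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "ecg_model"))
  x <- dataset$x
  labels <- as.factor(dataset$labels)
  classes <- levels(labels)
  if (length(classes) != model$spec$n_classes)
    ecg_stop("LabelError", "dataset has %d classes but model head outputs %d",
             length(classes), model$spec$n_classes)
  if (anyNA(labels)) ecg_stop("LabelError", "labels outside vocabulary")
  y <- as.integer(labels)
  model <- set_strategy(model, config$strategy)

  sp <- stratified_split(labels, config$split_fraction,
                         derive_seed(config$seed, "split"))
  w <- class_weights(factor(labels[sp$train], levels = classes))

  lr0 <- config$initial_lr
  if (is.null(lr0))
    lr0 <- find_lr(model, x[sp$train, , , drop = FALSE], y[sp$train], w, config)

  opt <- opt_new(config$optimizer, model$params, model$trainable)
  n_tr <- length(sp$train)
  bs <- min(config$batch_size, n_tr)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), eval_loss = numeric(0),
                     eval_weighted_f1 = numeric(0))
  best_loss <- Inf; best_epoch <- NA_integer_
  best_params <- NULL; best_state <- NULL; best_f1 <- NULL
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr0 * config$lr_decay_gamma^(epoch - 1)
    ep_loss <- 0; ep_n <- 0; finite_seen <- FALSE
    with_seed(derive_seed(config$seed, sprintf("epoch%03d", epoch)), {
      order <- sample(sp$train)
      for (b in seq_len(ceiling(n_tr / bs))) {
        idx <- order[((b - 1) * bs + 1):min(b * bs, n_tr)]
        fw <- nn_train_batch(model, x[idx, , , drop = FALSE], y[idx], w)
        model <- fw$model
        if (is.finite(fw$loss)) {
          finite_seen <- TRUE
          ep_loss <- ep_loss + fw$loss * length(idx); ep_n <- ep_n + length(idx)
          st <- opt_step(opt, model$params, fw$grads, lr, config)
          opt <- st$opt
          model$params <- st$params
        }
      }
    })
    if (!finite_seen)
      ecg_stop("DivergenceError", "loss non-finite for a full epoch (epoch %d)", epoch)

    ev <- evaluate_split(model, x, y, sp$eval, w, length(classes))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / max(ep_n, 1),
                                   eval_loss = ev$loss,
                                   eval_weighted_f1 = ev$wf1))
    if (is.finite(ev$loss) && ev$loss < best_loss) {
      best_loss <- ev$loss; best_epoch <- epoch
      best_params <- clone_params(model$params); best_state <- model$state
      best_f1 <- ev$per_class_f1
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$early_stop_patience) break
  }

  if (!is.null(best_params)) {
    model$params <- best_params
    model$state <- best_state
  }
  report <- structure(list(
    n_samples = length(y),
    label_distribution = as.list(table(labels)),
    classes = classes,
    base_model = model$spec$architecture %||% "imported",
    strategy = config$strategy,
    initial_lr = lr0,
    history = hist,
    best_epoch = best_epoch,
    best_eval_loss = best_loss,
    per_class_f1 = stats::setNames(as.numeric(best_f1), classes),
    eval_weighted_f1 = hist$eval_weighted_f1[match(best_epoch, hist$epoch)],
    n_train = n_tr, n_eval = length(sp$eval),
    train_indices = sp$train, eval_indices = sp$eval
  ), class = "train_report")
  list(model = model, report = report)
}

evaluate_split <- function(model, x, y, idx, w, K) {
  bs <- 64L
  logits <- matrix(NA_real_, length(idx), K)
  for (b in seq_len(ceiling(length(idx) / bs))) {
    sub <- idx[((b - 1) * bs + 1):min(b * bs, length(idx))]
    logits[((b - 1) * bs + 1):min(b * bs, length(idx)), ] <-
      model_forward(model, x[sub, , , drop = FALSE], training = FALSE)$logits
  }
  ce <- weighted_ce(logits, y[idx], w)
  pred <- max.col(logits, ties.method = "first")
  pf1 <- f1_score(y[idx], pred, K, average = "none")
  list(loss = ce$loss, per_class_f1 = pf1,
       wf1 = f1_score(y[idx], pred, K, average = "weighted"))
}

#' Write a training report to disk
#'
#' Emits `<stem>.json` (full report) and `<stem>_epochs.csv` (per-epoch
#' losses).
#'
#' @param report a `train_report` from [fit()].
#' @param stem output path without extension.
#' @return invisibly, the JSON path.
#' @export
write_train_report <- function(report, stem) {
  jsonlite::write_json(unclass(report), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.csv(report$history, paste0(stem, "_epochs.csv"), row.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d samples, %d classes, base %s (%s)\n",
              x$n_samples, length(x$classes), x$base_model, x$strategy))
  cat(sprintf("  epochs run: %d, best epoch: %d (eval loss %.4f, weighted F1 %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_eval_loss, x$eval_weighted_f1))
  invisible(x)
}
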