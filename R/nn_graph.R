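#' @useDynLib ecgtune, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Computation-graph machinery.
#
# A model is a DAG of named nodes over batched 1-D signals. Internally a batch
# is an array (L, C, N): time x channels x batch; the public forward contract
# is batch-first [N x C x L] to match the interchange-format convention.
# Parameter groups are keyed by node id, each with a per-group trainable flag,
# and exactly one node is designated as the classification head.
#
# Execution happens in compiled code: the node list plus parameters are
# compiled to a flat spec and handed to cpp_graph_run, which performs the
# forward pass, optionally the class-weighted cross-entropy and the backward
# pass, all without surfacing intermediate activations to R.
# ---------------------------------------------------------------------------

nn_node <- function(id, op, inputs, attrs = list()) {
  list(id = id, op = op, inputs = inputs, attrs = attrs)
}

node_has_params <- function(node) {
  node$op %in% c("conv", "dwconv", "bn", "linear")
}

#' Number of trainable scalar parameters in a model
#'
#' Sums the element counts of all parameter groups whose trainable flag is
#' set. Frozen groups (see [set_strategy()]) contribute zero.
#'
#' @param model a model built by [build_model()] or imported by
#'   [import_model()].
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ecg_model"))
  total <- 0L
  for (id in names(model$params)) {
    if (!isTRUE(model$trainable[[id]])) next
    total <- total + sum(vapply(model$params[[id]], length, integer(1)))
  }
  total
}

n_parameters_all <- function(model) {
  sum(vapply(model$params, function(p) sum(vapply(p, length, integer(1))), numeric(1)))
}

# convert batch-first [N x C x L] input array to internal (L, C, N) layout
batch_to_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x)) # single record C x L
  aperm(x, c(3L, 2L, 1L))
}

OP_CODES <- c(input = 0L, conv = 1L, linear = 1L, dwconv = 2L, bn = 3L,
              relu = 4L, maxpool3 = 5L, avgpool = 6L, gap = 7L, add = 8L,
              concat = 9L)

# Propagates whether gradients must flow out of each node: a node's output
# gradient is needed iff it (or an ancestor) holds a trainable group.
# Head-only fine-tuning therefore never back-propagates through the frozen
# backbone.
needs_grad_map <- function(model) {
  ng <- list()
  for (node in model$nodes) {
    own <- node_has_params(node) && isTRUE(model$trainable[[node$id]])
    up <- any(vapply(node$inputs, function(i) isTRUE(ng[[i]]), logical(1)))
    ng[[node$id]] <- own || up
  }
  ng
}

# flatten the model into the executor's node spec (0-based input indices)
compile_graph <- function(model) {
  ids <- names(model$nodes)
  pos <- stats::setNames(seq_along(ids) - 1L, ids)
  ng <- needs_grad_map(model)
  spec <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    node <- model$nodes[[i]]
    p <- model$params[[node$id]]
    s <- list(op = unname(OP_CODES[[node$op]]),
              inputs = unname(pos[node$inputs]),
              need_gx = any(vapply(node$inputs, function(j) isTRUE(ng[[j]]),
                                   logical(1))),
              need_pg = node_has_params(node) &&
                        isTRUE(model$trainable[[node$id]]))
    if (node$op %in% c("conv", "linear")) {
      s$k <- if (node$op == "linear") 1L else node$attrs$k
      s$w <- p$w
      s$b <- p$b
    } else if (node$op == "dwconv") {
      s$k <- node$attrs$k
      s$w <- p$w
    } else if (node$op == "bn") {
      st <- model$state[[node$id]]
      s$gamma <- p$gamma; s$beta <- p$beta
      s$rmean <- st$rmean; s$rvar <- st$rvar
      s$eps <- node$attrs$eps; s$momentum <- node$attrs$momentum
    } else if (node$op == "avgpool") {
      s$k <- node$attrs$k
    }
    spec[[i]] <- s
  }
  spec
}

apply_bn_updates <- function(model, bn_updates) {
  ids <- names(model$nodes)
  for (i in seq_along(bn_updates)) {
    u <- bn_updates[[i]]
    if (!is.null(u))
      model$state[[ids[i]]] <- list(rmean = as.numeric(u$rmean),
                                    rvar = as.numeric(u$rvar))
  }
  model
}

# forward pass; x is batch-first [N x C x L]. Returns list(logits [N x K],
# model) - the model comes back because training-mode forward updates the
# batch-norm running statistics.
model_forward <- function(model, x, training = FALSE, spec = NULL) {
  if (is.null(spec)) spec <- compile_graph(model)
  r <- cpp_graph_run(spec, batch_to_cube(x), training, NULL, NULL, FALSE)
  if (training) model <- apply_bn_updates(model, r$bn_updates)
  list(logits = r$logits, model = model)
}

# one training step's forward + loss + backward. y: 1-based integer classes;
# w: per-class weights. Returns loss, logits, per-group gradients (named by
# node id) and the model with refreshed batch-norm statistics.
nn_train_batch <- function(model, x, y, w, training = TRUE, spec = NULL) {
  if (is.null(spec)) spec <- compile_graph(model)
  r <- cpp_graph_run(spec, batch_to_cube(x), training,
                     as.integer(y), as.numeric(w), TRUE)
  if (training) model <- apply_bn_updates(model, r$bn_updates)
  ids <- names(model$nodes)
  grads <- list()
  for (i in seq_along(r$grads)) {
    g <- r$grads[[i]]
    if (is.null(g)) next
    p <- model$params[[ids[i]]]
    for (nm in names(g)) # match the parameter group's storage shape
      g[[nm]] <- if (is.matrix(p[[nm]])) matrix(g[[nm]], nrow(p[[nm]]))
                 else as.numeric(g[[nm]])
    grads[[ids[i]]] <- g
  }
  list(loss = r$loss, logits = r$logits, grads = grads, model = model)
}

# ---------------------------------------------------------------------------
# parameter utilities
# ---------------------------------------------------------------------------

# deterministic checksum of one parameter group (used by freezing audits)
param_checksum <- function(group) {
  v <- unlist(lapply(group, as.numeric), use.names = FALSE)
  sum(v * seq_along(v)) # order-sensitive linear hash
}

model_checksums <- function(model) {
  vapply(model$params, param_checksum, numeric(1))
}

clone_params <- function(params) lapply(params, function(g) lapply(g, identity))

shape_trace <- function(model) {
  # channel count and time length at every node output (L = 0 means the node
  # output is a (C x N) matrix, i.e. pooled over time)
  sh <- list(input = c(C = model$spec$in_channels, L = model$spec$n_samples))
  for (node in model$nodes) {
    if (node$id == "input") next
    a <- sh[[node$inputs[1]]]
    sh[[node$id]] <- switch(node$op,
      conv = c(C = node$attrs$out_ch, L = a[["L"]]),
      dwconv = a,
      bn = a, relu = a, maxpool3 = a,
      avgpool = c(C = a[["C"]], L = a[["L"]] %/% node$attrs$k),
      gap = c(C = a[["C"]], L = 1),
      linear = c(C = node$attrs$d_out, L = 1),
      add = a,
      concat = c(C = sum(vapply(node$inputs, function(i) sh[[i]][["C"]], numeric(1))),
                 L = a[["L"]]),
      stop("unknown op: ", node$op))
  }
  sh
}
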