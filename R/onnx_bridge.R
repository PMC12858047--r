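# ---------------------------------------------------------------------------
# Model interchange: classification-head adaptation, layer freezing, and
# ONNX import/export (Opset <= 20) with a dynamic batch dimension.
# ---------------------------------------------------------------------------

#' Replace the classification head for a new label set
#'
#' The designated head (the final affine map: a linear layer or a 1x1
#' convolution feeding the graph output) is replaced by a freshly initialized
#' map of matching input width and `n_classes_new` outputs. Every other
#' parameter group is preserved bit-identically.
#'
#' @param model an `ecg_model` (native or imported).
#' @param n_classes_new new number of classes.
#' @param seed seed for the new head's initialization.
#' @return the adapted model.
#' @export
adapt_head <- function(model, n_classes_new, seed = 42L) {
  stopifnot(inherits(model, "ecg_model"))
  hid <- model$head
  if (is.null(hid) || is.null(model$nodes[[hid]]))
    ecg_stop("HeadNotFound", "model has no identified affine classification head")
  node <- model$nodes[[hid]]
  n_classes_new <- as.integer(n_classes_new)
  with_seed(seed, {
    if (node$op == "linear") {
      model$params[[hid]] <- init_linear(n_classes_new, node$attrs$d_in,
                                         bias = !is.null(model$params[[hid]]$b))
      model$nodes[[hid]]$attrs$d_out <- n_classes_new
    } else if (node$op == "conv" && node$attrs$k == 1L) {
      model$params[[hid]] <- init_conv(n_classes_new, node$attrs$in_ch, 1L,
                                       bias = !is.null(model$params[[hid]]$b))
      model$nodes[[hid]]$attrs$out_ch <- n_classes_new
    } else {
      ecg_stop("HeadNotFound", "designated head '%s' is not an affine map", hid)
    }
  })
  model$spec$n_classes <- n_classes_new
  model
}

#' Set the fine-tuning strategy
#'
#' `"head"` freezes everything except the classification head; `"full"` makes
#' every parameter group trainable. Toggling is idempotent.
#'
#' @param model an `ecg_model`.
#' @param strategy `"head"` or `"full"`.
#' @return the model with trainable flags set.
#' @export
set_strategy <- function(model, strategy = c("full", "head")) {
  strategy <- match.arg(strategy)
  for (id in names(model$params))
    model$trainable[[id]] <- (strategy == "full") || identical(id, model$head)
  model
}

# ---------------------------------------------------------------------------
# export
# ---------------------------------------------------------------------------

ONNX_EXPORT_OPSET <- 17L
ONNX_MAX_OPSET <- 20L

#' Export a model to ONNX
#'
#' Serializes the graph with float32 weights and a dynamic ("batch") leading
#' dimension, so the exported file runs at any batch size. The byte stream is
#' deterministic: exporting the same model twice gives identical files.
#'
#' @param model an `ecg_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "ecg_model"))
  raw <- tryCatch(onnx_serialize_model(model),
                  error = function(e) ecg_stop("ExportError", conditionMessage(e)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw, con)
  invisible(path)
}

#' Import an ONNX classifier
#'
#' Parses a serialized classifier graph (Opset 20 and below, single waveform
#' input) into a trainable in-memory model. The classification head is
#' identified as the last affine-family node (Gemm, or Conv with kernel 1) on
#' the path to the graph output. Operators outside the supported vocabulary
#' raise a `ConversionError` naming the operator.
#'
#' @param path ONNX file path.
#' @return an `ecg_model` with `meta$source_opset`, `meta$original_n_classes`
#'   and the identified head.
#' @export
import_model <- function(path) {
  raw <- tryCatch(readBin(path, "raw", file.size(path)),
                  error = function(e) ecg_stop("ConversionError", "cannot read '%s'", path))
  if (length(raw) < 8) ecg_stop("ConversionError", "file too short to be a model graph")
  msg <- tryCatch(onnx_parse_model(raw),
                  error = function(e) {
                    if (inherits(e, "ecgtune_error")) stop(e)
                    ecg_stop("ConversionError", "corrupt model file: %s",
                             conditionMessage(e))
                  })
  msg
}
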