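# ---------------------------------------------------------------------------
# ONNX serialization: a self-contained protobuf wire-format writer/parser for
# the operator vocabulary this package emits (Conv, BatchNormalization, Relu,
# MaxPool, AveragePool, GlobalAveragePool, Gemm, Concat, Add, Flatten).
# Weights travel as float32 raw data; the graph input carries a dynamic
# "batch" leading dimension. Serialization is deterministic: no timestamps,
# no randomness, so byte-identical files come from identical models.
# ---------------------------------------------------------------------------

# -- protobuf wire primitives (write) ---------------------------------------

pb_varint <- function(x) {
  x <- as.numeric(x)
  if (x < 0) stop("negative varint not supported")
  if (x < 128) return(as.raw(x))
  out <- raw(0)
  while (x >= 128) {
    out <- c(out, as.raw(bitwOr(as.integer(x %% 128), 128L)))
    x <- floor(x / 128)
  }
  c(out, as.raw(x))
}

pb_key <- function(field, wire) pb_varint(field * 8 + wire)
pb_int <- function(field, x) c(pb_key(field, 0), pb_varint(x))
pb_bytes <- function(field, payload) {
  c(pb_key(field, 2), pb_varint(length(payload)), payload)
}
pb_str <- function(field, s) pb_bytes(field, charToRaw(s))
pb_float <- function(field, x) {
  c(pb_key(field, 5), writeBin(as.numeric(x), raw(), size = 4, endian = "little"))
}
pb_packed_varints <- function(field, xs) {
  pb_bytes(field, do.call(c, lapply(xs, pb_varint)))
}
pb_cat <- function(...) do.call(c, Filter(length, list(...)))

# -- ONNX message builders ---------------------------------------------------

# TensorProto: dims=1, data_type=2 (1 = FLOAT), name=8, raw_data=9
onnx_tensor <- function(name, dims, values) {
  pb_cat(pb_packed_varints(1, dims),
         pb_int(2, 1),
         pb_str(8, name),
         pb_bytes(9, writeBin(as.numeric(values), raw(), size = 4,
                              endian = "little")))
}

# AttributeProto: name=1, f=2, i=3, t=5, ints=7, type=20
onnx_attr_int <- function(name, v) {
  pb_cat(pb_str(1, name), pb_int(3, v), pb_int(20, 2))
}
onnx_attr_float <- function(name, v) {
  pb_cat(pb_str(1, name), pb_float(2, v), pb_int(20, 1))
}
onnx_attr_ints <- function(name, vs) {
  pb_cat(pb_str(1, name), pb_packed_varints(7, vs), pb_int(20, 7))
}

# NodeProto: input=1, output=2, name=3, op_type=4, attribute=5
onnx_node <- function(op_type, name, inputs, outputs, attrs = list()) {
  pb_cat(do.call(c, c(lapply(inputs, function(i) pb_str(1, i)), list(raw(0)))),
         do.call(c, c(lapply(outputs, function(o) pb_str(2, o)), list(raw(0)))),
         pb_str(3, name),
         pb_str(4, op_type),
         if (length(attrs)) do.call(c, lapply(attrs, function(a) pb_bytes(5, a))))
}

# ValueInfoProto: name=1, type=2 { tensor_type=1 { elem_type=1, shape=2 } }
onnx_value_info <- function(name, dims) {
  dim_msgs <- lapply(dims, function(d) {
    if (is.character(d)) pb_str(2, d) else pb_int(1, d)
  })
  shape <- do.call(c, lapply(dim_msgs, function(m) pb_bytes(1, m)))
  ttype <- pb_cat(pb_int(1, 1), pb_bytes(2, shape))
  pb_cat(pb_str(1, name), pb_bytes(2, pb_bytes(1, ttype)))
}

# -- model graph -> ONNX -----------------------------------------------------

onnx_serialize_model <- function(model) {
  spec <- model$spec
  nodes <- list()
  inits <- list()
  emit <- function(x) nodes[[length(nodes) + 1L]] <<- x
  init <- function(x) inits[[length(inits) + 1L]] <<- x

  for (node in model$nodes) {
    id <- node$id
    if (id == "input") next
    p <- model$params[[id]]
    ins <- node$inputs
    switch(node$op,
      conv = {
        k <- node$attrs$k
        wname <- paste0(id, ".weight")
        # my layout w(o, c*k+j) row-major-flattens to ONNX [Cout, Cin, k]
        init(onnx_tensor(wname, c(node$attrs$out_ch, node$attrs$in_ch, k),
                         as.numeric(t(p$w))))
        cins <- c(ins[1], wname)
        if (!is.null(p$b)) {
          bname <- paste0(id, ".bias")
          init(onnx_tensor(bname, length(p$b), p$b))
          cins <- c(cins, bname)
        }
        emit(onnx_node("Conv", id, cins, id, list(
          onnx_attr_ints("dilations", 1),
          onnx_attr_int("group", 1),
          onnx_attr_ints("kernel_shape", k),
          onnx_attr_ints("pads", c((k - 1) / 2, (k - 1) / 2)),
          onnx_attr_ints("strides", 1))))
      },
      dwconv = {
        k <- node$attrs$k; ch <- node$attrs$ch
        wname <- paste0(id, ".weight")
        # my layout w(j, c) column-major-flattens to ONNX [C, 1, k]
        init(onnx_tensor(wname, c(ch, 1, k), as.numeric(p$w)))
        emit(onnx_node("Conv", id, c(ins[1], wname), id, list(
          onnx_attr_ints("dilations", 1),
          onnx_attr_int("group", ch),
          onnx_attr_ints("kernel_shape", k),
          onnx_attr_ints("pads", c((k - 1) / 2, (k - 1) / 2)),
          onnx_attr_ints("strides", 1))))
      },
      bn = {
        st <- model$state[[id]]
        for (piece in c("scale", "B", "mean", "var")) {
          v <- switch(piece, scale = p$gamma, B = p$beta,
                      mean = st$rmean, var = st$rvar)
          init(onnx_tensor(paste0(id, ".", piece), length(v), v))
        }
        emit(onnx_node("BatchNormalization", id,
                       c(ins[1], paste0(id, ".", c("scale", "B", "mean", "var"))),
                       id, list(
          onnx_attr_float("epsilon", node$attrs$eps),
          onnx_attr_float("momentum", 1 - node$attrs$momentum))))
      },
      relu = emit(onnx_node("Relu", id, ins[1], id)),
      maxpool3 = emit(onnx_node("MaxPool", id, ins[1], id, list(
        onnx_attr_ints("kernel_shape", 3),
        onnx_attr_ints("pads", c(1, 1)),
        onnx_attr_ints("strides", 1)))),
      avgpool = emit(onnx_node("AveragePool", id, ins[1], id, list(
        onnx_attr_ints("kernel_shape", node$attrs$k),
        onnx_attr_ints("pads", c(0, 0)),
        onnx_attr_ints("strides", node$attrs$k)))),
      gap = {
        emit(onnx_node("GlobalAveragePool", id, ins[1], paste0(id, ".pooled")))
        emit(onnx_node("Flatten", paste0(id, ".flat"), paste0(id, ".pooled"),
                       id, list(onnx_attr_int("axis", 1))))
      },
      linear = {
        wname <- paste0(id, ".weight")
        init(onnx_tensor(wname, dim(p$w), as.numeric(t(p$w)))) # [out, in] row-major
        cins <- c(ins[1], wname)
        if (!is.null(p$b)) {
          bname <- paste0(id, ".bias")
          init(onnx_tensor(bname, length(p$b), p$b))
          cins <- c(cins, bname)
        }
        emit(onnx_node("Gemm", id, cins, id, list(
          onnx_attr_float("alpha", 1), onnx_attr_float("beta", 1),
          onnx_attr_int("transB", 1))))
      },
      add = emit(onnx_node("Add", id, ins, id)),
      concat = emit(onnx_node("Concat", id, ins, id,
                              list(onnx_attr_int("axis", 1)))),
      ecg_stop("ExportError", "operator '%s' has no interchange mapping", node$op))
  }

  out_id <- model$output
  graph <- pb_cat(
    do.call(c, lapply(nodes, function(n) pb_bytes(1, n))),
    pb_str(2, "ecg_classifier"),
    do.call(c, lapply(inits, function(t) pb_bytes(5, t))),
    pb_bytes(11, onnx_value_info("input", list("batch", spec$in_channels,
                                               spec$n_samples))),
    pb_bytes(12, onnx_value_info(out_id, list("batch", spec$n_classes))))

  opset <- pb_int(2, ONNX_EXPORT_OPSET) # domain omitted = default ai.onnx
  pb_cat(pb_int(1, 8),                  # ir_version
         pb_str(2, "ecgtune"),
         pb_str(3, "0.1.0"),
         pb_bytes(7, graph),
         pb_bytes(8, opset))
}

# -- protobuf wire primitives (read) ----------------------------------------

pb_read_varint <- function(raw, pos) {
  val <- 0; mult <- 1
  repeat {
    if (pos > length(raw)) stop("truncated varint")
    b <- as.integer(raw[pos]); pos <- pos + 1L
    val <- val + (b %% 128) * mult
    if (b < 128) break
    mult <- mult * 128
  }
  list(val = val, pos = pos)
}

pb_fields <- function(raw) {
  pos <- 1L; n <- length(raw)
  fields <- list()
  while (pos <= n) {
    v <- pb_read_varint(raw, pos); pos <- v$pos
    field <- v$val %/% 8; wire <- v$val %% 8
    if (wire == 0) {
      v <- pb_read_varint(raw, pos); val <- v$val; pos <- v$pos
    } else if (wire == 2) {
      v <- pb_read_varint(raw, pos); len <- v$val; pos <- v$pos
      if (pos + len - 1 > n) stop("truncated length-delimited field")
      val <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
    } else if (wire == 5) {
      val <- raw[pos:(pos + 3)]; pos <- pos + 4L
    } else if (wire == 1) {
      val <- raw[pos:(pos + 7)]; pos <- pos + 8L
    } else stop("unsupported wire type ", wire)
    fields[[length(fields) + 1L]] <- list(field = field, wire = wire, val = val)
  }
  fields
}

pb_get <- function(fields, field) Filter(function(f) f$field == field, fields)
pb_get1 <- function(fields, field) {
  hits <- pb_get(fields, field)
  if (length(hits)) hits[[length(hits)]]$val else NULL
}
pb_as_string <- function(val) if (is.null(val) || !length(val)) "" else rawToChar(val)
pb_packed_ints <- function(val) {
  if (is.null(val)) return(numeric(0))
  pos <- 1L; out <- numeric(0)
  while (pos <= length(val)) {
    v <- pb_read_varint(val, pos)
    out <- c(out, v$val); pos <- v$pos
  }
  out
}
pb_as_float <- function(val) readBin(val, "numeric", 1, size = 4, endian = "little")

# -- ONNX -> model graph -----------------------------------------------------

onnx_parse_tensor <- function(raw) {
  f <- pb_fields(raw)
  dims <- numeric(0)
  for (d in pb_get(f, 1)) {
    dims <- c(dims, if (d$wire == 0) d$val else pb_packed_ints(d$val))
  }
  dtype <- pb_get1(f, 2) %||% 1
  name <- pb_as_string(pb_get1(f, 8))
  rawdata <- pb_get1(f, 9)
  vals <- if (!is.null(rawdata)) {
    if (dtype == 1) readBin(rawdata, "numeric", length(rawdata) %/% 4, size = 4,
                            endian = "little")
    else if (dtype == 7) readBin(rawdata, "integer", length(rawdata) %/% 8, size = 8,
                                 endian = "little")
    else ecg_stop("ConversionError", "unsupported tensor data type %d", dtype)
  } else {
    fd <- pb_get(f, 4) # packed float_data
    if (length(fd)) readBin(fd[[1]]$val, "numeric", length(fd[[1]]$val) %/% 4,
                            size = 4, endian = "little")
    else numeric(0)
  }
  list(name = name, dims = dims, values = vals)
}

onnx_parse_attr <- function(raw) {
  f <- pb_fields(raw)
  list(name = pb_as_string(pb_get1(f, 1)),
       f = { v <- pb_get1(f, 2); if (!is.null(v)) pb_as_float(v) },
       i = pb_get1(f, 3),
       ints = pb_packed_ints(pb_get1(f, 7)))
}

onnx_parse_node <- function(raw) {
  f <- pb_fields(raw)
  attrs <- lapply(pb_get(f, 5), function(a) onnx_parse_attr(a$val))
  names(attrs) <- vapply(attrs, `[[`, "", "name")
  list(inputs = vapply(pb_get(f, 1), function(x) pb_as_string(x$val), ""),
       outputs = vapply(pb_get(f, 2), function(x) pb_as_string(x$val), ""),
       name = pb_as_string(pb_get1(f, 3)),
       op_type = pb_as_string(pb_get1(f, 4)),
       attrs = attrs)
}

onnx_parse_value_info <- function(raw) {
  f <- pb_fields(raw)
  name <- pb_as_string(pb_get1(f, 1))
  dims <- list()
  tt <- pb_get1(f, 2)
  if (!is.null(tt)) {
    tf <- pb_fields(tt)
    tens <- pb_get1(tf, 1)
    if (!is.null(tens)) {
      shf <- pb_fields(tens)
      shape <- pb_get1(shf, 2)
      if (!is.null(shape)) {
        for (d in pb_get(pb_fields(shape), 1)) {
          df <- pb_fields(d$val)
          dv <- pb_get1(df, 1)
          dims[[length(dims) + 1L]] <- if (!is.null(dv)) dv
                                       else pb_as_string(pb_get1(df, 2))
        }
      }
    }
  }
  list(name = name, dims = dims)
}

onnx_attr_ints_of <- function(node, name, default = NULL) {
  a <- node$attrs[[name]]
  if (is.null(a)) return(default)
  if (length(a$ints)) a$ints else a$i
}

onnx_parse_model <- function(raw) {
  f <- pb_fields(raw)
  graph_raw <- pb_get1(f, 7)
  if (is.null(graph_raw)) ecg_stop("ConversionError", "no graph in model file")
  for (op in pb_get(f, 8)) {
    of <- pb_fields(op$val)
    domain <- pb_as_string(pb_get1(of, 1))
    version <- pb_get1(of, 2) %||% 0
    if (domain %in% c("", "ai.onnx") && version > ONNX_MAX_OPSET)
      ecg_stop("UnsupportedOpset", "model requires Opset %d (> %d)",
               version, ONNX_MAX_OPSET)
  }
  source_opset <- {
    ops <- pb_get(f, 8)
    if (length(ops)) {
      of <- pb_fields(ops[[1]]$val)
      pb_get1(of, 2) %||% NA_integer_
    } else NA_integer_
  }

  g <- pb_fields(graph_raw)
  tensors <- lapply(pb_get(g, 5), function(t) onnx_parse_tensor(t$val))
  names(tensors) <- vapply(tensors, `[[`, "", "name")
  onodes <- lapply(pb_get(g, 1), function(n) onnx_parse_node(n$val))
  inputs <- lapply(pb_get(g, 11), function(v) onnx_parse_value_info(v$val))
  outputs <- lapply(pb_get(g, 12), function(v) onnx_parse_value_info(v$val))
  graph_inputs <- setdiff(vapply(inputs, `[[`, "", "name"), names(tensors))
  if (length(graph_inputs) != 1)
    ecg_stop("ConversionError", "expected a single waveform input, found %d",
             length(graph_inputs))
  in_info <- inputs[[match(graph_inputs, vapply(inputs, `[[`, "", "name"))]]
  in_dims <- in_info$dims
  in_channels <- if (length(in_dims) >= 2 && is.numeric(in_dims[[2]]))
    as.integer(in_dims[[2]]) else NA_integer_
  n_samples <- if (length(in_dims) >= 3 && is.numeric(in_dims[[3]]))
    as.integer(in_dims[[3]]) else NA_integer_

  onnx_graph_to_model(onodes, tensors, graph_inputs,
                      vapply(outputs, `[[`, "", "name")[1],
                      in_channels, n_samples, source_opset)
}

onnx_graph_to_model <- function(onodes, tensors, input_name, output_name,
                                in_channels, n_samples, source_opset) {
  gb_nodes <- list(input = nn_node("input", "input", character(0)))
  params <- list(); state <- list()
  alias <- stats::setNames("input", input_name) # tensor name -> my node id
  resolve <- function(nm) {
    if (nm %in% names(alias)) unname(alias[[nm]])
    else ecg_stop("ConversionError", "tensor '%s' produced by no supported node", nm)
  }
  chan <- c(input = in_channels) # channel bookkeeping for depthwise detection

  for (on in onodes) {
    id <- if (nzchar(on$name)) on$name else on$outputs[1]
    data_in <- setdiff(on$inputs, names(tensors))
    my_in <- vapply(data_in, resolve, "")
    out_name <- on$outputs[1]
    op <- on$op_type
    if (op == "Conv") {
      w <- tensors[[intersect(on$inputs, names(tensors))[1]]]
      k <- as.integer(onnx_attr_ints_of(on, "kernel_shape", utils::tail(w$dims, 1)))[1]
      strides <- onnx_attr_ints_of(on, "strides", 1)
      pads <- onnx_attr_ints_of(on, "pads", c(0, 0))
      group <- as.integer(onnx_attr_ints_of(on, "group", 1))
      if (any(strides != 1) || !all(pads == (k - 1) / 2))
        ecg_stop("ConversionError",
                 "Conv with stride %s / pads %s unsupported (same-padding, stride 1 only)",
                 paste(strides, collapse = ","), paste(pads, collapse = ","))
      cout <- w$dims[1]
      bias_name <- setdiff(intersect(on$inputs, names(tensors)),
                           w$name)
      b <- if (length(bias_name)) tensors[[bias_name[1]]]$values
      if (group > 1) {
        if (w$dims[2] != 1 || group != cout)
          ecg_stop("ConversionError", "grouped Conv other than depthwise unsupported")
        # ONNX [C,1,k] row-major raw -> my (k, C)
        wm <- matrix(w$values, nrow = k)
        gb_nodes[[id]] <- nn_node(id, "dwconv", my_in, list(k = k, ch = cout))
        params[[id]] <- list(w = wm)
        chan[id] <- cout
      } else {
        cin <- w$dims[2]
        wm <- t(matrix(w$values, nrow = cin * k, ncol = cout)) # row-major undo
        gb_nodes[[id]] <- nn_node(id, "conv", my_in,
                                  list(k = k, in_ch = cin, out_ch = cout))
        params[[id]] <- list(w = wm, b = b)
        chan[id] <- cout
      }
    } else if (op == "BatchNormalization") {
      tn <- intersect(on$inputs, names(tensors))
      if (length(tn) != 4)
        ecg_stop("ConversionError", "BatchNormalization needs 4 stored tensors")
      eps <- if (!is.null(on$attrs$epsilon)) on$attrs$epsilon$f else 1e-5
      mom <- if (!is.null(on$attrs$momentum)) 1 - on$attrs$momentum$f else 0.1
      ch <- length(tensors[[tn[1]]]$values)
      gb_nodes[[id]] <- nn_node(id, "bn", my_in,
                                list(eps = eps, momentum = mom, ch = ch))
      params[[id]] <- list(gamma = tensors[[tn[1]]]$values,
                           beta = tensors[[tn[2]]]$values)
      state[[id]] <- list(rmean = tensors[[tn[3]]]$values,
                          rvar = tensors[[tn[4]]]$values)
      chan[id] <- ch
    } else if (op == "Relu") {
      gb_nodes[[id]] <- nn_node(id, "relu", my_in)
      chan[id] <- chan[[my_in[1]]]
    } else if (op == "MaxPool") {
      k <- onnx_attr_ints_of(on, "kernel_shape")
      if (!identical(as.numeric(k), 3) ||
          !all(onnx_attr_ints_of(on, "strides", 1) == 1) ||
          !all(onnx_attr_ints_of(on, "pads", 0) == 1))
        ecg_stop("ConversionError", "MaxPool variant unsupported (kernel 3, stride 1 only)")
      gb_nodes[[id]] <- nn_node(id, "maxpool3", my_in)
      chan[id] <- chan[[my_in[1]]]
    } else if (op == "AveragePool") {
      k <- as.integer(onnx_attr_ints_of(on, "kernel_shape"))[1]
      if (!all(onnx_attr_ints_of(on, "strides", 1) == k) ||
          !all(onnx_attr_ints_of(on, "pads", 0) == 0))
        ecg_stop("ConversionError", "AveragePool variant unsupported (kernel == stride only)")
      gb_nodes[[id]] <- nn_node(id, "avgpool", my_in, list(k = k))
      chan[id] <- chan[[my_in[1]]]
    } else if (op == "GlobalAveragePool") {
      gb_nodes[[id]] <- nn_node(id, "gap", my_in)
      chan[id] <- chan[[my_in[1]]]
    } else if (op == "Flatten") {
      alias[out_name] <- my_in[1] # no-op after global pooling
      next
    } else if (op == "Gemm") {
      w <- tensors[[intersect(on$inputs, names(tensors))[1]]]
      transB <- onnx_attr_ints_of(on, "transB", 0)
      wm <- if (isTRUE(transB == 1)) t(matrix(w$values, nrow = w$dims[2]))
            else matrix(w$values, nrow = w$dims[1], byrow = TRUE)
      bias_name <- setdiff(intersect(on$inputs, names(tensors)), w$name)
      b <- if (length(bias_name)) tensors[[bias_name[1]]]$values
      gb_nodes[[id]] <- nn_node(id, "linear", my_in,
                                list(d_in = ncol(wm), d_out = nrow(wm)))
      params[[id]] <- list(w = wm, b = b)
      chan[id] <- nrow(wm)
    } else if (op == "Add") {
      gb_nodes[[id]] <- nn_node(id, "add", my_in)
      chan[id] <- chan[[my_in[1]]]
    } else if (op == "Concat") {
      gb_nodes[[id]] <- nn_node(id, "concat", my_in)
      chan[id] <- sum(vapply(my_in, function(i) chan[[i]], numeric(1)))
    } else {
      ecg_stop("ConversionError", "cannot convert operator '%s'", op)
    }
    alias[out_name] <- id
  }

  out_id <- resolve(output_name)

  # head: the affine-family node (Gemm or 1x1 Conv) closest to the output
  anc <- character(0); frontier <- out_id
  while (length(frontier)) {
    anc <- c(anc, frontier)
    frontier <- unique(unlist(lapply(frontier, function(i) gb_nodes[[i]]$inputs)))
    frontier <- setdiff(frontier, c(anc, "input"))
  }
  head <- NULL
  for (i in rev(seq_along(gb_nodes))) {
    nd <- gb_nodes[[i]]
    if (!(nd$id %in% anc)) next
    if (nd$op == "linear" || (nd$op == "conv" && nd$attrs$k == 1L)) {
      head <- nd$id
      break
    }
  }
  if (is.null(head))
    ecg_stop("HeadNotFound", "no affine classification head on the output path")
  n_classes <- if (gb_nodes[[head]]$op == "linear") gb_nodes[[head]]$attrs$d_out
               else gb_nodes[[head]]$attrs$out_ch

  trainable <- stats::setNames(as.list(rep(TRUE, length(params))), names(params))
  structure(list(nodes = gb_nodes, params = params, state = state,
                 trainable = trainable, output = out_id, head = head,
                 spec = list(architecture = "imported",
                             in_channels = in_channels, n_samples = n_samples,
                             n_classes = as.integer(n_classes)),
                 meta = list(source_opset = source_opset,
                             original_n_classes = as.integer(n_classes))),
            class = "ecg_model")
}
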