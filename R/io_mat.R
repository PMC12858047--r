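# Minimal MATLAB level-5 (.mat) reader: little-endian files, plain numeric
# matrices (double/single/int8..int32), small-data-element encoding, no
# compression. The first 2-D numeric variable is taken as the signal;
# variables named fs (or sampling_rate) and gain are honored when present.

mat_read_element <- function(raw, at) {
  type <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
  if (bitwAnd(type, bitwShiftL(65535L, 16L)) != 0L) {
    # small data element: size in upper half-word
    size <- bitwShiftR(type, 16L)
    type <- bitwAnd(type, 65535L)
    list(type = type, size = size, data_at = at + 4L, next_at = at + 8L)
  } else {
    size <- readBin(raw[(at + 4L):(at + 7L)], "integer", size = 4, endian = "little")
    pad <- (8L - size %% 8L) %% 8L
    list(type = type, size = size, data_at = at + 8L, next_at = at + 8L + size + pad)
  }
}

mat_numeric <- function(raw, el) {
  if (el$size == 0) return(numeric(0))
  bytes <- raw[el$data_at:(el$data_at + el$size - 1L)]
  switch(as.character(el$type),
    "1" = as.numeric(readBin(bytes, "integer", el$size, 1, signed = TRUE)),
    "2" = as.numeric(readBin(bytes, "integer", el$size, 1, signed = FALSE)),
    "3" = as.numeric(readBin(bytes, "integer", el$size / 2, 2, signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(bytes, "integer", el$size / 2, 2, signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(bytes, "integer", el$size / 4, 4, endian = "little")),
    "6" = as.numeric(readBin(bytes, "numeric", el$size / 4, 4, endian = "little")),
    "7" = as.numeric(readBin(bytes, "numeric", el$size / 4, 4, endian = "little")),
    "9" = readBin(bytes, "numeric", el$size / 8, 8, endian = "little"),
    ecg_stop("ReadError", "unsupported MAT data type %d", el$type))
}

mat_read <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128 + 8)
    ecg_stop("ReadError", "not a MAT v5 file (too short)")
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") ecg_stop("ReadError", "only little-endian MAT files supported")
  vars <- list()
  at <- 129L
  while (at + 8L <= length(raw)) {
    el <- mat_read_element(raw, at)
    if (el$type == 14L) { # miMATRIX
      sub_at <- el$data_at
      flags <- mat_read_element(raw, sub_at)
      class_id <- as.integer(raw[flags$data_at])
      dims_el <- mat_read_element(raw, flags$next_at)
      dims <- as.integer(mat_numeric(raw, dims_el))
      name_el <- mat_read_element(raw, dims_el$next_at)
      nm <- rawToChar(raw[name_el$data_at:(name_el$data_at + name_el$size - 1L)])
      if (class_id %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)) {
        data_el <- mat_read_element(raw, name_el$next_at)
        vals <- mat_numeric(raw, data_el)
        if (length(vals) == prod(dims) && length(dims) == 2L)
          vars[[nm]] <- matrix(vals, dims[1], dims[2]) # MATLAB is column-major
      }
    }
    if (el$next_at <= at) ecg_stop("ReadError", "corrupt MAT element chain")
    at <- el$next_at
  }
  if (!length(vars)) ecg_stop("ReadError", "no numeric matrix found in MAT file")
  vars
}

mat_read_ecg <- function(path) {
  vars <- mat_read(path)
  fs <- NULL; gain <- NULL; sig <- NULL
  for (nm in names(vars)) {
    v <- vars[[nm]]
    low <- tolower(nm)
    if (low %in% c("fs", "sampling_rate", "samplingrate") && length(v) == 1) fs <- as.numeric(v)
    else if (low == "gain" && length(v) == 1) gain <- as.numeric(v)
    else if (is.null(sig) && length(v) > 1) sig <- v
  }
  if (is.null(sig)) ecg_stop("ReadError", "no signal matrix found in MAT file")
  list(signal = sig, fs = fs, gain = gain)
}
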