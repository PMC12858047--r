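# Minimal NPY (v1.0) reader/writer and NPZ reader. The format is a fixed
# magic, a python-dict header giving dtype/order/shape, then raw data.

npy_write <- function(x, path) {
  x <- as.matrix(x)
  shape <- sprintf("(%d, %d)", nrow(x), ncol(x))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape)
  # pad so that magic(6) + version(2) + len(2) + header is a multiple of 64
  total <- 6 + 2 + 2 + nchar(header) + 1
  pad <- (64 - total %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(x)), con, size = 8, endian = "little") # C order
  invisible(path)
}

npy_parse_header <- function(raw) {
  if (length(raw) < 10 || raw[1] != as.raw(0x93) ||
      rawToChar(raw[2:6]) != "NUMPY")
    ecg_stop("ReadError", "not an NPY file")
  major <- as.integer(raw[7])
  if (major == 1) {
    hlen <- as.integer(raw[9]) + 256L * as.integer(raw[10])
    hstart <- 11L
  } else {
    hlen <- sum(as.integer(raw[9:12]) * 256^(0:3))
    hstart <- 13L
  }
  header <- rawToChar(raw[hstart:(hstart + hlen - 1)])
  descr <- regmatches(header, regexec("'descr'\\s*:\\s*'([^']+)'", header))[[1]][2]
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_s <- regmatches(header, regexec("'shape'\\s*:\\s*\\(([^)]*)\\)", header))[[1]][2]
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  list(descr = descr, fortran = fortran, shape = shape,
       offset = hstart + hlen - 1L)
}

npy_read <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  h <- npy_parse_header(raw)
  typ <- switch(h$descr,
    "<f8" = list(what = "numeric", size = 8), "<f4" = list(what = "numeric", size = 4),
    "<i8" = list(what = "integer", size = 8), "<i4" = list(what = "integer", size = 4),
    "<i2" = list(what = "integer", size = 2), "|i1" = list(what = "integer", size = 1),
    "<u2" = list(what = "integer", size = 2, unsigned = TRUE),
    ecg_stop("ReadError", "unsupported NPY dtype '%s'", h$descr))
  n <- prod(pmax(h$shape, 1L))
  if (length(h$shape) == 0) n <- 1L
  data <- readBin(raw[(h$offset + 1L):length(raw)], typ$what, n = n,
                  size = typ$size, endian = "little",
                  signed = !isTRUE(typ$unsigned) || typ$size > 2)
  data <- as.numeric(data)
  if (length(data) < n) ecg_stop("ReadError", "NPY payload truncated")
  if (length(h$shape) <= 1) return(matrix(data, nrow = 1))
  if (length(h$shape) != 2) ecg_stop("ReadError", "only 1-D/2-D NPY supported")
  if (h$fortran) matrix(data, h$shape[1], h$shape[2])
  else t(matrix(data, h$shape[2], h$shape[1]))
}

npz_read <- function(path) {
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- tryCatch(utils::unzip(path, exdir = tmp),
                    warning = function(w) ecg_stop("ReadError", "corrupt NPZ archive"),
                    error = function(e) ecg_stop("ReadError", "corrupt NPZ archive"))
  npys <- sort(files[grepl("\\.npy$", files)])
  if (!length(npys)) ecg_stop("ReadError", "NPZ archive holds no arrays")
  npy_read(npys[1])
}
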