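# Shared fixtures: tiny architectures for fast graph tests, binary-container
# writers (DICOM waveform, MAT v5) used to exercise the readers, and a clean
# single-record generator.

tiny_spec <- function(arch = "inceptiontime", K = 2L) {
  model_spec(arch, in_channels = 2L, n_samples = 32L, n_classes = K, nf = 2L)
}

clean_synth_config <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0.02, wander_mv = 0.05), list(...))
  do.call(synth_config, args)
}

# ---- minimal stored (uncompressed) ZIP writer for NPZ fixtures -------------

# bitwise XOR on non-negative doubles below 2^32 (avoids signed-int overflow)
bitwXor_num <- function(a, b) {
  r <- 0; m <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + m
    a <- (a - ab) / 2; b <- (b - bb) / 2; m <- m * 2
  }
  r
}

# table-driven CRC-32 (IEEE) over a raw vector
crc32_ieee <- local({
  tab <- NULL
  function(bytes) {
    if (is.null(tab)) {
      t0 <- numeric(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (c %% 2 == 1) bitwXor_num(3988292384, floor(c / 2))
               else floor(c / 2)
        t0[i + 1] <- c
      }
      tab <<- t0
    }
    crc <- 4294967295
    for (b in as.integer(bytes))
      crc <- bitwXor_num(tab[bitwXor(as.integer(crc %% 256), b) + 1],
                         floor(crc / 256))
    bitwXor_num(crc, 4294967295)
  }
})

zip_u <- function(x, size) {
  # little-endian unsigned write, accepting doubles up to 2^32 - 1
  out <- raw(size)
  x <- as.numeric(x)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  out
}

# store one member without compression
write_stored_zip <- function(path, name, data) {
  crc <- crc32_ieee(data)
  fname <- charToRaw(name)
  local_hdr <- c(charToRaw("PK"), as.raw(c(3, 4)), zip_u(20, 2), zip_u(0, 2),
                 zip_u(0, 2), zip_u(0, 2), zip_u(0, 2), zip_u(crc, 4),
                 zip_u(length(data), 4), zip_u(length(data), 4),
                 zip_u(length(fname), 2), zip_u(0, 2), fname)
  central <- c(charToRaw("PK"), as.raw(c(1, 2)), zip_u(20, 2), zip_u(20, 2),
               zip_u(0, 2), zip_u(0, 2), zip_u(0, 2), zip_u(0, 2), zip_u(crc, 4),
               zip_u(length(data), 4), zip_u(length(data), 4),
               zip_u(length(fname), 2), zip_u(0, 2), zip_u(0, 2), zip_u(0, 2),
               zip_u(0, 2), zip_u(0, 4), zip_u(0, 4), fname)
  eocd <- c(charToRaw("PK"), as.raw(c(5, 6)), zip_u(0, 2), zip_u(0, 2),
            zip_u(1, 2), zip_u(1, 2), zip_u(length(central), 4),
            zip_u(length(local_hdr) + length(data), 4), zip_u(0, 2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(local_hdr, data, central, eocd), con)
  invisible(path)
}

# a small separable dataset at reduced input size for training-loop tests:
# records are full preprocessing products of the generator at 100 Hz/10 s
small_dataset <- function(n = 30, seed = 7) {
  generate_dataset(synth_config(n_records = n, seed = seed))
}

# ---- DICOM waveform fixture (explicit VR little endian) --------------------

dcm_u <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

dcm_el <- function(group, elem, vr, payload) {
  payload <- as.raw(payload)
  hdr <- c(dcm_u(group, 2), dcm_u(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(hdr, raw(2), dcm_u(length(payload), 4), payload)
  else
    c(hdr, dcm_u(length(payload), 2), payload)
}

dcm_item <- function(payload) c(dcm_u(0xFFFE, 2), dcm_u(0xE000, 2),
                                dcm_u(length(payload), 4), payload)

dcm_text <- function(s) { # even-length padded text payload
  if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
  charToRaw(s)
}

# writes adu values (n_ch x n_samp integer matrix) with per-channel
# sensitivity mV/ADU
write_dicom_fixture <- function(path, adu, fs, sensitivity, labels = NULL) {
  n_ch <- nrow(adu); n_samp <- ncol(adu)
  chan_items <- raw(0)
  for (c in seq_len(n_ch)) {
    item <- c(
      if (!is.null(labels)) dcm_el(0x003A, 0x0203, "SH", dcm_text(labels[c])),
      dcm_el(0x003A, 0x0210, "DS", dcm_text(format(sensitivity, digits = 10))))
    chan_items <- c(chan_items, dcm_item(item))
  }
  wave <- dcm_u(as.integer(adu), 2) # column-major = channel-interleaved
  mux <- c(dcm_el(0x003A, 0x0005, "US", dcm_u(n_ch, 2)),
           dcm_el(0x003A, 0x0010, "UL", dcm_u(n_samp, 4)),
           dcm_el(0x003A, 0x001A, "DS", dcm_text(format(fs))),
           dcm_el(0x003A, 0x0200, "SQ", chan_items),
           dcm_el(0x5400, 0x1004, "US", dcm_u(16, 2)),
           dcm_el(0x5400, 0x1010, "OW", wave))
  body <- dcm_el(0x5400, 0x0100, "SQ", dcm_item(mux))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# ---- MAT v5 fixture --------------------------------------------------------

mat_sub_el <- function(type, data) {
  data <- as.raw(data)
  pad <- raw((8 - length(data) %% 8) %% 8)
  c(writeBin(as.integer(type), raw(), 4, endian = "little"),
    writeBin(length(data), raw(), 4, endian = "little"), data, pad)
}

mat_var <- function(name, m) {
  m <- as.matrix(m)
  inner <- c(
    mat_sub_el(6, writeBin(c(6L, 0L), raw(), 4, endian = "little")),   # flags: mxDOUBLE
    mat_sub_el(5, writeBin(as.integer(dim(m)), raw(), 4, endian = "little")),
    mat_sub_el(1, charToRaw(name)),
    mat_sub_el(9, writeBin(as.numeric(m), raw(), 8, endian = "little")))
  mat_sub_el(14, inner)
}

write_mat_fixture <- function(path, vars) {
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, test fixture"))
  tail <- c(raw(8), as.raw(c(0x00, 0x01)), charToRaw("IM"))
  body <- do.call(c, lapply(names(vars), function(nm) mat_var(nm, vars[[nm]])))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, tail, body), con)
  invisible(path)
}
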