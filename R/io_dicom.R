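# Minimal DICOM waveform reader (explicit VR, little endian): walks the data
# set, descends into the WaveformSequence (5400,0100) and collects the
# channel count, sample count, sampling frequency, per-channel sensitivity
# (mV per stored unit) and the interleaved 16-bit WaveformData. Vendor
# specifics beyond this core are out of scope; reading is sufficient for
# waveform exchange, writing is not supported.

dcm_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
dcm_u32 <- function(raw, at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))

dcm_walk <- function(raw, at, end, handler) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (at + 7 <= end) {
    group <- dcm_u16(raw, at); elem <- dcm_u16(raw, at + 2L)
    if (group == 0xFFFE) { # item delimiters inside sequences
      len <- dcm_u32(raw, at + 4L)
      at <- at + 8L
      if (elem == 0xE000) next # item start handled by caller descending
      next
    }
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, at + 8L)
      hdr <- 12L
    } else {
      len <- dcm_u16(raw, at + 6L)
      hdr <- 8L
    }
    if (len == 0xFFFFFFFF) ecg_stop("ReadError", "undefined-length element unsupported")
    body_at <- at + hdr
    handler(group, elem, vr, body_at, len)
    at <- body_at + len
  }
  invisible(NULL)
}

dcm_items <- function(raw, at, end) {
  # returns list of c(start, length) for items of a sequence body
  items <- list()
  while (at + 7 <= end) {
    group <- dcm_u16(raw, at); elem <- dcm_u16(raw, at + 2L)
    len <- dcm_u32(raw, at + 4L)
    at <- at + 8L
    if (group == 0xFFFE && elem == 0xE000) {
      items[[length(items) + 1L]] <- c(at, len)
      at <- at + len
    } else break
  }
  items
}

dicom_read <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    ecg_stop("ReadError", "not a DICOM file (missing DICM marker)")
  env <- new.env()
  env$n_ch <- NA_integer_; env$n_samp <- NA_integer_; env$fs <- NA_real_
  env$sens <- numeric(0); env$labels <- character(0); env$data <- NULL
  env$bits <- 16L

  chan_handler <- function(group, elem, vr, at, len) {
    if (group == 0x003A && elem == 0x0210)
      env$sens <- c(env$sens, as.numeric(rawToChar(raw[at:(at + len - 1L)])))
    if (group == 0x003A && elem == 0x0203)
      env$labels <- c(env$labels, trimws(rawToChar(raw[at:(at + len - 1L)])))
  }
  mux_handler <- function(group, elem, vr, at, len) {
    if (group == 0x003A && elem == 0x0005) env$n_ch <- dcm_u16(raw, at)
    if (group == 0x003A && elem == 0x0010) env$n_samp <- dcm_u32(raw, at)
    if (group == 0x003A && elem == 0x001A)
      env$fs <- as.numeric(rawToChar(raw[at:(at + len - 1L)]))
    if (group == 0x003A && elem == 0x0200) {
      for (item in dcm_items(raw, at, at + len - 1L))
        dcm_walk(raw, item[1], item[1] + item[2] - 1L, chan_handler)
    }
    if (group == 0x5400 && elem == 0x1004) env$bits <- dcm_u16(raw, at)
    if (group == 0x5400 && elem == 0x1010) env$data <- raw[at:(at + len - 1L)]
  }
  top_handler <- function(group, elem, vr, at, len) {
    if (group == 0x5400 && elem == 0x0100) {
      for (item in dcm_items(raw, at, at + len - 1L))
        dcm_walk(raw, item[1], item[1] + item[2] - 1L, mux_handler)
    }
  }
  dcm_walk(raw, 133L, length(raw), top_handler)

  if (is.null(env$data) || is.na(env$n_ch) || is.na(env$fs))
    ecg_stop("ReadError", "no WaveformSequence found in DICOM file")
  if (env$bits != 16L)
    ecg_stop("ReadError", "only 16-bit waveform data supported")
  vals <- readBin(env$data, "integer", n = length(env$data) %/% 2L, size = 2,
                  endian = "little", signed = TRUE)
  n_ch <- env$n_ch
  n_samp <- if (is.na(env$n_samp)) length(vals) %/% n_ch else env$n_samp
  m <- matrix(as.numeric(vals[seq_len(n_ch * n_samp)]), nrow = n_ch)
  sens <- if (length(env$sens) == n_ch) env$sens else rep(1 / 1000, n_ch)
  sig <- m * sens
  labels <- if (length(env$labels) == n_ch) env$labels else NULL
  ecg_record(sig, fs = env$fs, lead_names = labels,
             gain_adu_per_mv = 1 / sens[1],
             record_id = sub("\\.dcm$", "", basename(path)))
}
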