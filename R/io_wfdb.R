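# WFDB-style DAT+HEA pair: a plain-text header naming the record, signal
# count, sampling rate and sample count, one line per signal with the storage
# format and the ADU/mV gain; the .dat holds interleaved 16-bit little-endian
# integers (format 16 only).

wfdb_write <- function(record, hea_path, gain = NULL) {
  gain <- gain %||% record$gain_adu_per_mv %||% 1000
  stem <- sub("\\.hea$", "", hea_path)
  dat_name <- paste0(basename(stem), ".dat")
  nsig <- nrow(record$signal); nsamp <- ncol(record$signal)
  adu <- round(record$signal * gain)
  adu[adu > 32767] <- 32767; adu[adu < -32768] <- -32768
  lines <- c(sprintf("%s %d %g %d", basename(stem), nsig, record$fs, nsamp),
             sprintf("%s 16 %g/mV 16 0 %d 0 0 %s", dat_name, gain,
                     as.integer(adu[seq_len(nsig), 1]), record$lead_names))
  writeLines(lines, hea_path)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  # column-major flatten of [nsig x nsamp] is exactly the interleaved order
  writeBin(as.integer(adu), con, size = 2, endian = "little")
  invisible(hea_path)
}

wfdb_read <- function(path) {
  stem <- sub("\\.(hea|dat)$", "", path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) ecg_stop("ReadError", "missing header file '%s'", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) ecg_stop("ReadError", "malformed header line")
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  gains <- numeric(nsig); baselines <- numeric(nsig); leads <- character(nsig)
  dat_file <- NULL
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    dat_file <- f[1]
    if (f[2] != "16")
      ecg_stop("ReadError", "unsupported DAT storage format '%s' (only 16)", f[2])
    gspec <- f[3]
    base <- 0
    if (grepl("\\(", gspec)) {
      base <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gspec))
      gspec <- sub("\\(.*\\)", "", gspec)
    }
    gains[i] <- as.numeric(sub("/.*", "", gspec))
    baselines[i] <- base
    leads[i] <- if (length(f) >= 9) f[length(f)] else CANONICAL_LEADS[min(i, 12)]
  }
  if (any(!is.finite(gains) | gains == 0)) gains[!is.finite(gains) | gains == 0] <- 200
  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) ecg_stop("ReadError", "missing data file '%s'", dat)
  vals <- readBin(dat, "integer", n = nsig * nsamp, size = 2,
                  endian = "little", signed = TRUE)
  if (length(vals) < nsig * nsamp) ecg_stop("ReadError", "DAT payload truncated")
  m <- matrix(as.numeric(vals), nrow = nsig) # interleaved: sample-major
  sig <- (m - baselines) / gains
  ecg_record(sig, fs = fs, lead_names = leads, gain_adu_per_mv = gains[1],
             record_id = basename(stem))
}
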