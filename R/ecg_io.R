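# ---------------------------------------------------------------------------
# Format dispatch: read/write ECG waveforms across the supported container
# formats and the dataset manifest, yielding uniform `ecg_record`s.
# ---------------------------------------------------------------------------

#' Identify the container format of a waveform file
#'
#' Decides by file extension first (`.csv`, `.npy`/`.npz`, `.dcm`, `.mat`,
#' `.dat`/`.hea`, `.xml`), falling back to magic-byte inspection for unknown
#' extensions.
#'
#' @param path file path (must exist).
#' @return one of `"csv"`, `"npy"`, `"dicom"`, `"mat"`, `"dat"`, `"xml"`.
#' @export
sniff_format <- function(path) {
  if (!file.exists(path)) ecg_stop("ReadError", "file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext, csv = "csv", npy = "npy", npz = "npy", dcm = "dicom",
                mat = "mat", dat = "dat", hea = "dat", xml = "xml", NULL)
  if (!is.null(fmt)) return(fmt)
  head <- readBin(path, "raw", min(file.size(path), 256))
  if (length(head) >= 6 && head[1] == as.raw(0x93) &&
      rawToChar(head[2:6]) == "NUMPY") return("npy")
  if (length(head) >= 4 && rawToChar(head[1:4]) == "PK\x03\x04") return("npy")
  if (file.size(path) > 132 &&
      rawToChar(readBin(path, "raw", 132)[129:132]) == "DICM") return("dicom")
  if (length(head) >= 10 && grepl("^MATLAB 5\\.0", rawToChar(head[1:10]))) return("mat")
  txt <- suppressWarnings(tryCatch(rawToChar(head), error = function(e) ""))
  if (is.na(txt) || !all(validUTF8(txt))) txt <- ""
  if (grepl("^\\s*<", txt)) return("xml")
  if (grepl("^[-0-9eE+., \t\r\nIVaRLFvh\"']+$", txt) && grepl(",", txt)) return("csv")
  ecg_stop("UnsupportedFormat", "cannot identify format of '%s'", path)
}

#' Read an ECG waveform file
#'
#' Reads any supported container into an `ecg_record` in mV: a declared gain
#' is divided out, the lead axis is taken as the shorter axis when the
#' orientation is ambiguous (resting ECGs never exceed 16 leads; square
#' matrices keep rows as leads), and lead names come from the container when
#' present, else the canonical order is assumed positionally.
#'
#' @param path file path.
#' @param fs sampling-rate override in Hz; required for containers that do
#'   not embed one (csv, npy, mat without an `fs` variable).
#' @param gain ADU/mV gain override; when given, stored values are divided by
#'   it.
#' @param lead_names lead-name override.
#' @param format optional explicit format id (skips sniffing).
#' @return an `ecg_record`.
#' @export
read_ecg <- function(path, fs = NULL, gain = NULL, lead_names = NULL,
                     format = NULL) {
  fmt <- format %||% sniff_format(path)
  rid <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  res <- switch(fmt,
    csv = csv_read_ecg(path),
    npy = {
      sig <- if (grepl("\\.npz$", path, ignore.case = TRUE)) npz_read(path)
             else npy_read(path)
      list(signal = sig, fs = NULL, gain = NULL, lead_names = NULL)
    },
    dat = return(apply_overrides(wfdb_read(path), fs, gain, lead_names)),
    dicom = return(apply_overrides(dicom_read(path), fs, gain, lead_names)),
    mat = mat_read_ecg(path),
    xml = xmlecg_read(path),
    ecg_stop("UnsupportedFormat", "unsupported format '%s'", fmt))
  sig <- orient_leads(res$signal)
  if (!is.null(gain)) sig <- sig / gain
  else if (!is.null(res$gain) && fmt %in% c("mat")) sig <- sig / res$gain
  fs_use <- fs %||% res$fs
  if (is.null(fs_use))
    ecg_stop("MissingMetadata",
             "'%s' declares no sampling rate; supply fs explicitly", path)
  rec <- ecg_record(sig, fs = fs_use,
                    lead_names = lead_names %||% res$lead_names,
                    gain_adu_per_mv = gain %||% res$gain, record_id = rid)
  rec
}

apply_overrides <- function(rec, fs, gain, lead_names) {
  if (!is.null(fs)) rec$fs <- fs
  if (!is.null(lead_names)) rec$lead_names <- lead_names
  if (!is.null(gain)) {
    rec$signal <- rec$signal * (rec$gain_adu_per_mv %||% 1) / gain
    rec$gain_adu_per_mv <- gain
  }
  validate_ecg_record(rec)
}

# ambiguous orientation: the axis of length <= 16 is the lead axis; square
# matrices keep rows as leads
orient_leads <- function(sig) {
  sig <- as.matrix(sig)
  if (nrow(sig) > ncol(sig) && ncol(sig) <= 16) t(sig)
  else if (nrow(sig) > 16 && ncol(sig) <= 16) t(sig)
  else sig
}

csv_read_ecg <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  cells <- strsplit(first, ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells))))
  df <- tryCatch(utils::read.csv(path, header = has_header,
                                 check.names = FALSE),
                 error = function(e) ecg_stop("ReadError", "corrupt CSV: %s",
                                              conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) ecg_stop("ReadError", "non-numeric payload in CSV")
  }
  # CSV convention: one column per lead
  list(signal = t(unname(m)), fs = NULL, gain = NULL,
       lead_names = if (has_header) colnames(df))
}

#' Write an ECG waveform file
#'
#' Supported output formats: `csv` (one column per lead, header row of lead
#' names, full precision), `npy` (float64 mV) and `dat` (WFDB-style
#' DAT+HEA pair, 16-bit integers at the record's gain, default 1000 ADU/mV).
#' A written file read back with [read_ecg()] reproduces the signal within
#' 1e-6 mV (csv, npy) or the integer quantization step (dat).
#'
#' @param record an `ecg_record`.
#' @param path output path.
#' @param format `"csv"`, `"npy"` or `"dat"`.
#' @return invisibly, `path`.
#' @export
write_ecg <- function(record, path, format = c("csv", "npy", "dat")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    ecg_stop("WriteError", "directory '%s' does not exist", dirname(path))
  ok <- tryCatch({
    switch(format,
      csv = {
        df <- as.data.frame(t(record$signal))
        names(df) <- record$lead_names
        utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                         path, row.names = FALSE, quote = FALSE)
      },
      npy = npy_write(record$signal, path),
      dat = wfdb_write(record, if (grepl("\\.hea$", path)) path
                               else paste0(sub("\\.dat$", "", path), ".hea")))
    TRUE
  }, error = function(e) {
    if (inherits(e, "ecgtune_error")) stop(e)
    ecg_stop("WriteError", "cannot write '%s': %s", path, conditionMessage(e))
  })
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `record_path`, `patient_id`, `label` and
#' optionally `acquired_at`. The class vocabulary is the lexicographically
#' sorted set of distinct labels.
#'
#' @param path manifest CSV path.
#' @return a `dataset_manifest`: data frame with attribute `classes`.
#' @export
read_manifest <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) ecg_stop("ManifestError", "unreadable manifest: %s",
                                              conditionMessage(e)))
  if (nrow(df) == 0) ecg_stop("ManifestError", "manifest is empty")
  required <- c("record_path", "patient_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    ecg_stop("ManifestError", "manifest lacks column(s): %s",
             paste(missing, collapse = ", "))
  if (anyDuplicated(df$record_path))
    ecg_stop("ManifestError", "duplicate record_path entries in manifest")
  structure(df, classes = sort(unique(as.character(df$label))),
            class = c("dataset_manifest", "data.frame"))
}
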