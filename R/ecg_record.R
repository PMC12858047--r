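# The uniform in-memory representation of one ECG recording.

CANONICAL_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG record
#'
#' The package-wide container for one recording: a leads-by-samples matrix in
#' millivolt, its sampling rate and lead names, plus optional provenance
#' (original ADU/mV gain, patient and record identifiers, acquisition time).
#'
#' @param signal numeric matrix `[n_leads x n_samples]` in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector, one name per row of `signal`; defaults
#'   to the canonical 12-lead order (or `chN` beyond 12 leads).
#' @param gain_adu_per_mv original integer-coding gain, or `NULL`.
#' @param patient_id,record_id opaque identifier strings.
#' @param acquired_at acquisition timestamp (`POSIXct` or string), or `NULL`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = NULL, gain_adu_per_mv = NULL,
                       patient_id = NULL, record_id = "record",
                       acquired_at = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(lead_names)) {
    lead_names <- if (nrow(signal) <= 12) CANONICAL_LEADS[seq_len(nrow(signal))]
                  else paste0("ch", seq_len(nrow(signal)))
  }
  rec <- structure(list(signal = signal, fs = as.numeric(fs),
                        lead_names = as.character(lead_names),
                        gain_adu_per_mv = gain_adu_per_mv,
                        patient_id = patient_id, record_id = record_id,
                        acquired_at = acquired_at),
                   class = "ecg_record")
  validate_ecg_record(rec)
}

validate_ecg_record <- function(rec) {
  if (nrow(rec$signal) < 1 || ncol(rec$signal) < 1)
    ecg_stop("ReadError", "signal must have >= 1 lead and >= 1 sample")
  if (length(rec$lead_names) != nrow(rec$signal))
    ecg_stop("ReadError", "lead_names length (%d) != n_leads (%d)",
             length(rec$lead_names), nrow(rec$signal))
  if (!is.finite(rec$fs) || rec$fs <= 0)
    ecg_stop("MissingMetadata", "sampling rate must be a positive number")
  if (!all(is.finite(rec$signal)))
    ecg_stop("ReadError", "signal contains non-finite values")
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d leads x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  if (!is.null(x$gain_adu_per_mv))
    cat(sprintf("  original gain: %g ADU/mV\n", x$gain_adu_per_mv))
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$signal)
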