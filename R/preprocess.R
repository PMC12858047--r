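# ---------------------------------------------------------------------------
# Normalization pipeline: Fourier resampling to a unified rate, 12-lead and
# fixed-duration standardization, and millivolt/ADU gain standardization.
# Stage order is fixed: resample -> leads -> duration -> gain.
# ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' @param target_fs unified sampling rate in Hz (default 100).
#' @param target_leads canonical ordered lead set (default the standard 12).
#' @param target_duration_s standardized duration in seconds (default 10).
#' @param target_gain standardized integer-coding gain in ADU/mV
#'   (default 1000).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_fs = 100, target_leads = CANONICAL_LEADS,
                              target_duration_s = 10, target_gain = 1000) {
  stopifnot(target_fs > 0, target_duration_s > 0, target_gain > 0,
            length(target_leads) >= 1, length(target_leads) <= 16)
  structure(list(target_fs = target_fs, target_leads = target_leads,
                 target_duration_s = target_duration_s,
                 target_gain = target_gain),
            class = "preprocess_config")
}

round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Fourier-domain resampling
#'
#' Per-lead spectral resampling: the discrete Fourier transform is truncated
#' (downsampling) or zero-padded (upsampling) to the new length, with the
#' Nyquist bin split or folded so real signals stay real. Output length is
#' `round(n * fs_out / fs_in)` (half away from zero). Band-limited inputs are
#' reproduced essentially exactly.
#'
#' @param signal numeric matrix `[n_leads x n_samples]` (a vector is treated
#'   as one lead).
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return matrix `[n_leads x round(n * fs_out / fs_in)]`.
#' @export
resample_fft <- function(signal, fs_in, fs_out) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(fs_in > 0, fs_out > 0)
  n <- ncol(signal)
  if (n < 2) ecg_stop("DegenerateSignal", "need >= 2 samples to resample")
  if (fs_in == fs_out) return(signal)
  m <- as.integer(round_half_away(n * fs_out / fs_in))
  out <- matrix(0, nrow(signal), m)
  for (r in seq_len(nrow(signal))) {
    X <- stats::fft(signal[r, ])
    Y <- complex(m)
    h <- (min(n, m) - 1) %/% 2                 # strictly-below-Nyquist bins
    Y[1] <- X[1]
    if (h >= 1) {
      Y[2:(h + 1)] <- X[2:(h + 1)]
      Y[(m - h + 1):m] <- X[(n - h + 1):n]
    }
    if (m < n && m %% 2 == 0)                  # fold onto the new Nyquist bin
      Y[m / 2 + 1] <- X[m / 2 + 1] + X[n - m / 2 + 1]
    if (m > n && n %% 2 == 0) {                # split the old Nyquist bin
      Y[n / 2 + 1] <- X[n / 2 + 1] / 2
      Y[m - n / 2 + 1] <- Conj(X[n / 2 + 1]) / 2
    }
    out[r, ] <- Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
  }
  out
}

#' Standardize the lead set
#'
#' Maps named leads onto the canonical slots of `config$target_leads`
#' (case-insensitive); missing leads are zero-filled, extra leads dropped.
#' When the record's lead names are not drawn from the canonical vocabulary,
#' leads are assigned canonical names positionally.
#'
#' @param record an `ecg_record`.
#' @param config a [preprocess_config()].
#' @return an `ecg_record` with exactly the canonical leads, in order.
#' @export
standardize_leads <- function(record, config = preprocess_config()) {
  target <- config$target_leads
  have <- record$lead_names
  matched <- match(tolower(have), tolower(target))
  if (all(is.na(matched))) {
    # unnamed / non-canonical leads: positional assignment
    matched <- seq_along(have)
    matched[matched > length(target)] <- NA
  }
  out <- matrix(0, length(target), ncol(record$signal))
  keep <- which(!is.na(matched))
  out[matched[keep], ] <- record$signal[keep, ]
  record$signal <- out
  record$lead_names <- target
  record
}

#' Standardize the duration
#'
#' Crops over-length recordings to the first `target_duration_s` seconds and
#' zero-pads short ones at the end.
#'
#' @inheritParams standardize_leads
#' @return an `ecg_record` with exactly `target_duration_s * fs` samples.
#' @export
standardize_duration <- function(record, config = preprocess_config()) {
  n_target <- as.integer(round(record$fs * config$target_duration_s))
  n <- ncol(record$signal)
  if (n >= n_target) {
    record$signal <- record$signal[, seq_len(n_target), drop = FALSE]
  } else {
    pad <- matrix(0, nrow(record$signal), n_target - n)
    record$signal <- cbind(record$signal, pad)
  }
  record
}

#' Standardize the amplitude coding
#'
#' Keeps the signal in mV and attaches an integer-coded view at
#' `target_gain` ADU/mV: `adu = round(signal_mV * target_gain)`. The record's
#' declared gain becomes `target_gain`.
#'
#' @inheritParams standardize_leads
#' @return an `ecg_record` with elements `adu` (integer matrix) and
#'   `gain_adu_per_mv = target_gain`.
#' @export
standardize_gain <- function(record, config = preprocess_config()) {
  record$adu <- round(record$signal * config$target_gain)
  storage.mode(record$adu) <- "integer"
  record$gain_adu_per_mv <- config$target_gain
  record
}

#' Full normalization pipeline
#'
#' Composition resample -> leads -> duration -> gain. The output shape is
#' always `length(target_leads) x round(target_fs * target_duration_s)`
#' regardless of the input, and the pipeline is idempotent.
#'
#' @inheritParams standardize_leads
#' @return a standardized `ecg_record`.
#' @examples
#' rec <- generate_ecg("NORM", synth_config(fs = 500), seed = 7)
#' dim(preprocess(rec)$signal) # 12 x 1000
#' @export
preprocess <- function(record, config = preprocess_config()) {
  if (record$fs != config$target_fs) {
    record$signal <- resample_fft(record$signal, record$fs, config$target_fs)
    record$fs <- config$target_fs
  }
  record <- standardize_leads(record, config)
  record <- standardize_duration(record, config)
  standardize_gain(record, config)
}
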