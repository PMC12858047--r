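# ---------------------------------------------------------------------------
# R-peak detection (Pan-Tompkins-style), beat extraction, median beat and
# R-aligned time normalization.
# ---------------------------------------------------------------------------

#' Detect R peaks
#'
#' Pan-Tompkins-style detector on one lead (conventionally II): band-pass
#' 5-15 Hz, differentiate, square, moving-window integration over 150 ms,
#' then an adaptive signal/noise threshold with a 200 ms refractory period.
#' Peak positions are refined to the local maximum of the band-passed signal.
#'
#' @param record an `ecg_record` of at least 2 s duration.
#' @param lead lead name to analyse (default `"II"`); an error is raised when
#'   the lead is not present.
#' @return an `rpeaks` object: list with `indices` (1-based sample positions,
#'   strictly increasing, gaps >= 0.2 s) and `fs`.
#' @export
detect_r_peaks <- function(record, lead = "II") {
  li <- match(tolower(lead), tolower(record$lead_names))
  if (is.na(li)) ecg_stop("ReadError", "lead '%s' not present", lead)
  fs <- record$fs
  x <- record$signal[li, ]
  if (length(x) < 2 * fs) ecg_stop("NoBeatsDetected", "need >= 2 s of signal")
  if (stats::sd(x) < 1e-8) ecg_stop("NoBeatsDetected", "flat signal")

  hi <- min(15, 0.45 * fs / 2 * 2) # 15 Hz or just under Nyquist
  bf <- signal::butter(2, c(5, hi) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, x))
  der <- c(diff(filt), 0)
  sq <- der^2
  win <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  refractory <- round(0.2 * fs)
  # candidate local maxima of the integrated signal
  n <- length(integ)
  cand <- which(integ > c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf))
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) ecg_stop("NoBeatsDetected", "no candidate peaks")

  spki <- max(integ[seq_len(min(n, round(2 * fs)))]) * 0.6
  npki <- mean(integ[seq_len(min(n, round(2 * fs)))]) * 0.5
  peaks <- integer(0)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] >= thr) {
      if (length(peaks) && i - peaks[length(peaks)] < refractory) {
        # keep the stronger of the two competing peaks
        if (integ[i] > integ[peaks[length(peaks)]]) peaks[length(peaks)] <- i
        next
      }
      peaks <- c(peaks, i)
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) ecg_stop("NoBeatsDetected", "no peaks above threshold")

  # refine to the maximum of the band-passed signal near each detection
  half <- round(0.10 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi2 <- min(n, p + half)
    as.integer(lo + which.max(filt[lo:hi2]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory invariant after refinement
  keep <- c(TRUE, diff(refined) >= refractory)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refractory)
  }
  structure(list(indices = refined, fs = fs), class = "rpeaks")
}

#' Extract fixed-width beats around R peaks
#'
#' Windows of `window[1]` ms before to `window[2]` ms after each R index;
#' beats whose window leaves the recording are dropped.
#'
#' @param record an `ecg_record`.
#' @param rpeaks an `rpeaks` object from [detect_r_peaks()].
#' @param window `c(pre_ms, post_ms)`, default `c(250, 400)`.
#' @return array `[n_beats x n_leads x width]` with
#'   `width = round((pre + post) / 1000 * fs)`.
#' @export
extract_beats <- function(record, rpeaks, window = c(250, 400)) {
  if (!length(rpeaks$indices)) ecg_stop("NoBeatsDetected", "no R peaks supplied")
  fs <- record$fs
  pre <- round(window[1] / 1000 * fs)
  post <- round(window[2] / 1000 * fs)
  width <- pre + post
  n <- ncol(record$signal)
  ok <- rpeaks$indices[rpeaks$indices - pre + 1 >= 1 & rpeaks$indices + post <= n]
  if (!length(ok)) ecg_stop("NoBeatsDetected", "no complete beat window fits")
  beats <- array(0, c(length(ok), nrow(record$signal), width))
  for (b in seq_along(ok))
    beats[b, , ] <- record$signal[, (ok[b] - pre + 1):(ok[b] + post)]
  attr(beats, "peak_indices") <- ok
  beats
}

#' Median beat template
#'
#' Pointwise median across beats, per lead: a noise-robust beat template.
#'
#' @param beats array `[n_beats x n_leads x width]` from [extract_beats()].
#' @return matrix `[n_leads x width]`.
#' @export
median_beat <- function(beats) {
  if (is.null(dim(beats)) || dim(beats)[1] < 1)
    ecg_stop("NoBeatsDetected", "empty beat stack")
  apply(beats, c(2, 3), stats::median)
}

#' R-aligned time normalization
#'
#' Resamples each RR segment linearly to the median RR length and
#' concatenates them, yielding a rhythm-normalized recording covering the
#' span from the first to the last R peak.
#'
#' @param record an `ecg_record`.
#' @param rpeaks an `rpeaks` object with at least 3 peaks.
#' @return an `ecg_record` whose RR intervals all equal the median RR.
#' @export
align_r_peaks <- function(record, rpeaks) {
  idx <- rpeaks$indices
  if (length(idx) < 3) ecg_stop("NoBeatsDetected", "need >= 3 R peaks to align")
  med <- round(stats::median(diff(idx)))
  pieces <- vector("list", length(idx) - 1)
  for (s in seq_len(length(idx) - 1)) {
    seg <- record$signal[, idx[s]:idx[s + 1], drop = FALSE]
    src <- seq(0, 1, length.out = ncol(seg))
    dst <- seq(0, 1, length.out = med + 1)[seq_len(med)]
    pieces[[s]] <- t(apply(seg, 1, function(row) stats::approx(src, row, dst)$y))
  }
  out <- cbind(do.call(cbind, pieces), record$signal[, idx[length(idx)], drop = FALSE])
  rec <- record
  rec$signal <- out
  rec$record_id <- paste0(record$record_id, "_aligned")
  attr(rec, "rr_samples") <- med
  rec
}
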