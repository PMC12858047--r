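# ---------------------------------------------------------------------------
# Synthetic 12-lead ECG generator with known ground truth.
#
# Each beat is a sum of Gaussian bumps (P, Q, R, S, T) placed at fixed offsets
# around the R peak; a class may widen the QRS complex, shift the ST segment
# or scale the R amplitude. A fixed 12-entry projection vector scales the
# template per lead, emulating the amplitude pattern of the standard leads.
# Pink-ish realism (respiratory baseline wander, white measurement noise) is
# additive and optional. Ground-truth beat times are returned, which makes
# detector scoring exact.
# ---------------------------------------------------------------------------

# per-lead projection of the beat template (dimensionless, lead II = 1)
LEAD_PROJECTION <- c(I = 0.55, II = 1.00, III = 0.45, aVR = -0.75, aVL = 0.20,
                     aVF = 0.70, V1 = -0.35, V2 = 0.65, V3 = 0.95, V4 = 1.15,
                     V5 = 1.00, V6 = 0.80)

default_classes <- function() {
  list(
    NORM  = list(qrs_width = 1.0, st_offset = 0.00, r_amp = 1.0),
    WIDE  = list(qrs_width = 2.4, st_offset = 0.00, r_amp = 0.75), # BBB-like widened QRS
    STSHIFT = list(qrs_width = 1.0, st_offset = 0.25, r_amp = 1.1) # ischaemia-like ST shift
  )
}

#' Synthetic dataset configuration
#'
#' Defaults describe clean, clearly separable resting ECGs: three classes
#' (normal morphology, widened QRS, ST shift), heart rate 50-100 bpm, 5% RR
#' jitter, 0.05 mV white noise and 0.1 mV respiratory baseline wander at
#' 10-second duration and 100 Hz.
#'
#' @param n_records number of records (default 300, balanced over classes).
#' @param classes named list of morphology effects, each with `qrs_width`
#'   (multiplier), `st_offset` (mV) and `r_amp` (multiplier).
#' @param hr_range heart-rate range in bpm.
#' @param rr_jitter fractional standard deviation of RR intervals.
#' @param noise_sd additive white noise, mV.
#' @param wander_mv baseline-wander amplitude, mV.
#' @param fs sampling rate, Hz.
#' @param duration_s record duration, seconds.
#' @param gain ADU/mV gain declared when records are written to disk.
#' @param seed master seed; fixes all randomness.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_records = 300L, classes = default_classes(),
                         hr_range = c(50, 100), rr_jitter = 0.05,
                         noise_sd = 0.05, wander_mv = 0.1, fs = 100,
                         duration_s = 10, gain = 1000, seed = 1L) {
  stopifnot(length(classes) >= 1, fs > 0, duration_s > 0)
  structure(list(n_records = as.integer(n_records), classes = classes,
                 hr_range = hr_range, rr_jitter = rr_jitter,
                 noise_sd = noise_sd, wander_mv = wander_mv, fs = fs,
                 duration_s = duration_s, gain = gain, seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian-bump beat template evaluated at times t (seconds relative to the
# R peak); returns mV on the reference lead (II).
beat_template <- function(t, effect) {
  qw <- effect$qrs_width
  g <- function(mu, sd, amp) amp * exp(-0.5 * ((t - mu) / sd)^2)
  v <- g(-0.20, 0.025, 0.15) +                    # P
       g(-0.035 * qw, 0.012 * qw, -0.12) +        # Q
       g(0.00, 0.016 * qw, 1.0 * effect$r_amp) +  # R
       g(0.045 * qw, 0.014 * qw, -0.25) +         # S
       g(0.30, 0.055, 0.35)                       # T
  if (effect$st_offset != 0)
    v <- v + g(0.16, 0.07, effect$st_offset)      # ST segment shift
  v
}

#' Generate one synthetic ECG record
#'
#' @param class_id name of a class in `config$classes`.
#' @param config a [synth_config()].
#' @param seed integer seed for this record.
#' @param heart_rate optional fixed heart rate in bpm; drawn from
#'   `config$hr_range` when `NULL`.
#' @return an `ecg_record` with attribute `beat_times` (ground-truth R-peak
#'   times in seconds).
#' @export
generate_ecg <- function(class_id, config = synth_config(), seed = 1L,
                         heart_rate = NULL) {
  effect <- config$classes[[class_id]]
  if (is.null(effect)) ecg_stop("LabelError", "unknown class '%s'", class_id)
  with_seed(seed, {
    hr <- if (is.null(heart_rate))
      stats::runif(1, config$hr_range[1], config$hr_range[2]) else heart_rate
    rr <- 60 / hr
    beats <- numeric(0)
    t0 <- 0.3 # fixed first-beat offset keeps the beat count exact per rate
    while (t0 < config$duration_s - 0.05) {
      beats <- c(beats, t0)
      t0 <- t0 + rr * (1 + config$rr_jitter * stats::rnorm(1))
    }
    n <- round(config$fs * config$duration_s)
    tt <- (seq_len(n) - 1) / config$fs
    ref <- rep(0, n)
    for (b in beats) ref <- ref + beat_template(tt - b, effect)
    sig <- outer(LEAD_PROJECTION, ref)     # 12 x n
    if (config$wander_mv > 0) {
      ph <- stats::runif(12, 0, 2 * pi)
      wander <- config$wander_mv * sin(outer(ph, 2 * pi * 0.25 * tt, `+`))
      sig <- sig + wander
    }
    if (config$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(length(sig), sd = config$noise_sd),
                          nrow = nrow(sig))
    rec <- ecg_record(sig, fs = config$fs, lead_names = CANONICAL_LEADS,
                      gain_adu_per_mv = config$gain,
                      record_id = sprintf("syn_%s_%06d", class_id, seed))
    attr(rec, "beat_times") <- beats
    rec
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces balanced classes (up to rounding) and, if `dir` is given, writes
#' each record to disk rotating through the writable container formats (csv,
#' npy, dat) together with a dataset manifest, so the format readers are
#' exercised end to end. Records are also preprocessed to the standard
#' `12 x (fs * duration)` input tensor.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory for on-disk records + `manifest.csv`.
#' @param preprocess_cfg a [preprocess_config()] used to shape the model
#'   input tensor.
#' @return a `labeled_dataset`: list with `x` (array `[n x 12 x samples]`),
#'   `labels` (factor), `classes`, `records` (list of `ecg_record`),
#'   `beat_times` (list) and `manifest` (data frame when `dir` is given).
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL,
                             preprocess_cfg = NULL) {
  if (length(config$classes) < 2) ecg_stop("LabelError", "need >= 2 classes")
  if (is.null(preprocess_cfg))
    preprocess_cfg <- preprocess_config(target_fs = config$fs,
                                        target_duration_s = config$duration_s,
                                        target_gain = config$gain)
  classes <- names(config$classes)
  labels <- rep(classes, length.out = config$n_records) # round-robin balance
  formats <- c("csv", "npy", "dat")
  records <- vector("list", config$n_records)
  beat_times <- vector("list", config$n_records)
  rows <- NULL
  n_time <- round(preprocess_cfg$target_fs * preprocess_cfg$target_duration_s)
  x <- array(0, c(config$n_records, length(preprocess_cfg$target_leads), n_time))
  for (i in seq_len(config$n_records)) {
    rec <- generate_ecg(labels[i], config, seed = derive_seed(config$seed, sprintf("rec%05d", i)))
    rec$patient_id <- sprintf("P%05d", i)
    rec$record_id <- sprintf("R%05d", i)
    beat_times[[i]] <- attr(rec, "beat_times")
    records[[i]] <- rec
    pp <- preprocess(rec, preprocess_cfg)
    x[i, , ] <- pp$signal
    if (!is.null(dir)) {
      fmt <- formats[(i - 1) %% length(formats) + 1]
      path <- file.path(dir, sprintf("%s.%s", rec$record_id,
                                     if (fmt == "dat") "hea" else fmt))
      write_ecg(rec, path, fmt)
      rows <- rbind(rows, data.frame(record_path = basename(path),
                                     patient_id = rec$patient_id,
                                     label = labels[i]))
    }
  }
  manifest <- NULL
  if (!is.null(dir)) {
    manifest <- rows
    utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(x = x, labels = factor(labels, levels = classes),
                 classes = classes, records = records, beat_times = beat_times,
                 manifest = manifest),
            class = "labeled_dataset")
}

#' Assemble a labeled dataset from records
#'
#' Preprocesses a list of `ecg_record`s to the standard input tensor and pairs
#' them with labels.
#'
#' @param records list of `ecg_record`.
#' @param labels per-record labels (character or factor).
#' @param preprocess_cfg a [preprocess_config()].
#' @return a `labeled_dataset`.
#' @export
as_labeled_dataset <- function(records, labels,
                               preprocess_cfg = preprocess_config()) {
  stopifnot(length(records) == length(labels))
  labels <- as.factor(labels)
  n_time <- round(preprocess_cfg$target_fs * preprocess_cfg$target_duration_s)
  x <- array(0, c(length(records), length(preprocess_cfg$target_leads), n_time))
  for (i in seq_along(records))
    x[i, , ] <- preprocess(records[[i]], preprocess_cfg)$signal
  structure(list(x = x, labels = labels, classes = levels(labels),
                 records = records, beat_times = NULL, manifest = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records, %d classes (%s)\n",
              dim(x$x)[1], length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}
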