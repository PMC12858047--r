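test_that("detector finds the planted beats at fixed heart rates", {
  cfg <- clean_synth_config(rr_jitter = 0)
  rec60 <- generate_ecg("NORM", cfg, seed = 21, heart_rate = 60)
  rp <- detect_r_peaks(rec60)
  expect_equal(length(rp$indices), 10)
  gaps <- diff(rp$indices)
  expect_true(all(abs(gaps - rec60$fs) <= 1)) # 1.0 s +/- 1 sample

  rec120 <- generate_ecg("NORM", cfg, seed = 22, heart_rate = 120)
  expect_equal(length(detect_r_peaks(rec120)$indices), 20)
})

test_that("degenerate signals raise NoBeatsDetected", {
  flat <- ecg_record(matrix(0, 12, 1000), fs = 100)
  expect_error(detect_r_peaks(flat), class = "NoBeatsDetected")
  short <- ecg_record(matrix(rnorm(12 * 50), 12), fs = 100)
  expect_error(detect_r_peaks(short), class = "NoBeatsDetected")
  rec <- generate_ecg("NORM", clean_synth_config(), seed = 1)
  expect_error(detect_r_peaks(rec, lead = "nope"), class = "ReadError")
})

test_that("detector sensitivity and precision reach 0.95 from 40 to 180 bpm", {
  for (hr in c(40, 70, 100, 140, 180)) {
    planted <- 0; detected <- 0; matched <- 0
    for (s in 1:2) {
      rec <- generate_ecg("NORM", clean_synth_config(), seed = 100 + 7 * s + hr,
                          heart_rate = hr)
      truth <- attr(rec, "beat_times")
      det <- (detect_r_peaks(rec)$indices - 1) / rec$fs
      planted <- planted + length(truth)
      detected <- detected + length(det)
      matched <- matched + sum(vapply(truth, function(b) any(abs(det - b) <= 0.05),
                                      logical(1)))
    }
    expect_gte(matched / planted, 0.95)   # sensitivity
    expect_gte(matched / detected, 0.95)  # precision
  }
})

test_that("beat extraction windows and edge rules hold", {
  rec <- generate_ecg("NORM", clean_synth_config(rr_jitter = 0), seed = 5,
                      heart_rate = 60)
  rp <- detect_r_peaks(rec)
  beats <- extract_beats(rec, rp)
  width <- round((250 + 400) / 1000 * rec$fs)
  expect_equal(dim(beats)[2:3], c(12, width))
  expect_lte(dim(beats)[1], length(rp$indices))

  # a peak too close to the start is dropped
  fake <- structure(list(indices = c(3L, 500L), fs = rec$fs), class = "rpeaks")
  b2 <- extract_beats(rec, fake)
  expect_equal(dim(b2)[1], 1)
  expect_equal(attr(b2, "peak_indices"), 500L)

  # no complete window at all
  edge <- structure(list(indices = 2L, fs = rec$fs), class = "rpeaks")
  expect_error(extract_beats(rec, edge), class = "NoBeatsDetected")
})

test_that("median beat is robust and permutation invariant", {
  b <- array(0, c(3, 2, 5))
  template <- matrix(rnorm(10), 2, 5)
  for (i in 1:3) b[i, , ] <- template
  b[3, 1, 2] <- b[3, 1, 2] + 10 # single outlier loses 2-of-3 majority
  med <- median_beat(b)
  expect_equal(med, template)

  set.seed(4)
  b2 <- array(rnorm(5 * 2 * 7), c(5, 2, 7))
  perm <- sample(5)
  expect_equal(median_beat(b2), median_beat(b2[perm, , , drop = FALSE]))
  expect_error(median_beat(array(0, c(0, 2, 5))), class = "NoBeatsDetected")
})

test_that("R-aligned transform normalizes RR intervals to the median", {
  # regular rhythm: output equals input between first and last peak
  rec <- generate_ecg("NORM", clean_synth_config(noise_sd = 0, wander_mv = 0,
                                                 rr_jitter = 0),
                      seed = 6, heart_rate = 60)
  rp <- detect_r_peaks(rec)
  al <- align_r_peaks(rec, rp)
  span <- rec$signal[, rp$indices[1]:rp$indices[length(rp$indices)]]
  expect_equal(dim(al$signal), dim(span))
  expect_lt(max(abs(al$signal - span)), 1e-6)

  # alternating RR 0.8/1.2 s -> all aligned intervals equal the median (1.0 s)
  fs <- 100
  idx <- cumsum(c(50, rep(c(80, 120), 4))) # 9 peaks
  sig <- matrix(0, 1, 1200)
  sig[1, idx] <- 1
  rec2 <- ecg_record(sig, fs = fs, lead_names = "II")
  rp2 <- structure(list(indices = idx, fs = fs), class = "rpeaks")
  al2 <- align_r_peaks(rec2, rp2)
  expect_equal(attr(al2, "rr_samples"), 100)
  expect_equal(ncol(al2$signal), 8 * 100 + 1)

  expect_error(align_r_peaks(rec2, structure(list(indices = idx[1:2], fs = fs),
                                             class = "rpeaks")),
               class = "NoBeatsDetected")
  # 3 peaks -> exactly 2 aligned segments
  al3 <- align_r_peaks(rec2, structure(list(indices = idx[1:3], fs = fs),
                                       class = "rpeaks"))
  expect_equal(ncol(al3$signal), 2 * 100 + 1)
})
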