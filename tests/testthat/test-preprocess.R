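test_that("resampling length follows round(n * fs_out / fs_in)", {
  x <- matrix(rnorm(12 * 5000), 12)
  y <- resample_fft(x, 500, 100)
  expect_equal(dim(y), c(12, 1000))
  expect_identical(resample_fft(x, 500, 500), x)
  expect_error(resample_fft(matrix(1, 1, 1), 500, 100), class = "DegenerateSignal")
})

test_that("resampling matches the analytic sine oracle", {
  fs_in <- 500; fs_out <- 100; dur <- 10
  t_in <- seq(0, dur - 1 / fs_in, by = 1 / fs_in)
  x <- sin(2 * pi * 5 * t_in)
  y <- resample_fft(x, fs_in, fs_out)[1, ]
  t_out <- seq(0, dur - 1 / fs_out, by = 1 / fs_out)
  expect_lt(max(abs(y - sin(2 * pi * 5 * t_out))), 1e-6)
  # upsampling the other way as well
  up <- resample_fft(sin(2 * pi * 5 * t_out), fs_out, fs_in)[1, ]
  expect_lt(max(abs(up - x)), 1e-6)
})

test_that("resampling preserves RMS of band-limited signals within 1%", {
  set.seed(42)
  for (rep in 1:5) {
    # random band-limited signal: power below 40 Hz, sampled at 500 Hz
    n <- 5000
    spec <- complex(real = rnorm(n), imaginary = rnorm(n))
    keep <- c(seq_len(400), (n - 398):n)
    mask <- rep(0, n); mask[keep] <- 1; mask[1] <- 0
    X <- spec * mask
    X[(n:2)[1:399]] <- Conj(X[2:400]) # enforce conjugate symmetry
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    y <- resample_fft(x, 500, 100)[1, ]
    rms_ratio <- sqrt(mean(y^2)) / sqrt(mean(x^2))
    expect_lt(abs(rms_ratio - 1), 0.01)
  }
})

test_that("lead standardization fills, drops and passes through", {
  cfg <- preprocess_config()
  full <- ecg_record(matrix(rnorm(12 * 100), 12), fs = 100)
  expect_equal(standardize_leads(full, cfg)$signal, full$signal)

  eight <- ecg_record(matrix(1:800, 8, byrow = TRUE), fs = 100,
                      lead_names = c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  out <- standardize_leads(eight, cfg)
  expect_equal(nrow(out$signal), 12)
  expect_equal(out$lead_names, cfg$target_leads)
  zero_rows <- match(c("III", "aVR", "aVL", "aVF"), out$lead_names)
  expect_true(all(out$signal[zero_rows, ] == 0))
  expect_equal(out$signal[match("V1", out$lead_names), ],
               eight$signal[3, ])

  fifteen <- ecg_record(matrix(rnorm(15 * 50), 15), fs = 100,
                        lead_names = c(ecgtune:::CANONICAL_LEADS, "X", "Y", "Z"))
  expect_equal(nrow(standardize_leads(fifteen, cfg)$signal), 12)
})

test_that("duration standardization crops the start window and zero-pads the end", {
  cfg <- preprocess_config()
  exact <- ecg_record(matrix(rnorm(12 * 1000), 12), fs = 100)
  expect_equal(standardize_duration(exact, cfg)$signal, exact$signal)

  short <- ecg_record(matrix(1, 12, 600), fs = 100)
  out <- standardize_duration(short, cfg)
  expect_equal(ncol(out$signal), 1000)
  expect_true(all(out$signal[, 601:1000] == 0))
  expect_true(all(out$signal[, 1:600] == 1))

  long <- ecg_record(matrix(rep(1:1200, each = 12), 12), fs = 100)
  out <- standardize_duration(long, cfg)
  expect_equal(ncol(out$signal), 1000)
  expect_equal(out$signal[1, ], 1:1000)
})

test_that("gain standardization codes mV at the target gain", {
  cfg <- preprocess_config() # 1000 ADU/mV
  rec <- ecg_record(matrix(c(1.0, 0.0, -0.5, 0.0015), 1), fs = 100)
  out <- standardize_gain(rec, cfg)
  expect_identical(as.integer(out$adu[1, ]), c(1000L, 0L, -500L, 2L))
  expect_equal(out$gain_adu_per_mv, 1000)

  # a record imported at 200 ADU/mV codes 5x larger at 1000 ADU/mV
  vals <- seq(-1, 1, length.out = 21)
  rec200 <- ecg_record(matrix(round(vals * 200) / 200, 1), fs = 100)
  out200 <- standardize_gain(rec200, cfg)
  expect_identical(as.integer(out200$adu), as.integer(round(vals * 200) * 5))
})

test_that("full pipeline yields the standard shape and is idempotent", {
  cfg <- preprocess_config()
  raw <- ecg_record(matrix(rnorm(8 * 3500), 8), fs = 500,
                    lead_names = c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  out <- preprocess(raw, cfg) # 8 leads, 7 s @ 500 Hz in
  expect_equal(dim(out$signal), c(12, 1000))
  again <- preprocess(out, cfg)
  expect_identical(out$signal, again$signal)
  expect_identical(out$adu, again$adu)

  # an already-standard record passes through bitwise (gain step only recodes)
  std <- ecg_record(matrix(rnorm(12 * 1000), 12), fs = 100)
  expect_identical(preprocess(std, cfg)$signal, std$signal)
})
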