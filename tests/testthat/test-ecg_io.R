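test_that("format sniffing uses extensions then magic bytes", {
  d <- withr::local_tempdir()
  paths <- c(csv = "a.csv", npy = "a.npy", dicom = "rec.dcm", mat = "m.mat",
             dat = "r.dat", xml = "x.xml")
  for (p in paths) file.create(file.path(d, p))
  for (i in seq_along(paths))
    expect_equal(sniff_format(file.path(d, paths[i])), names(paths)[i])

  # extensionless NPY is identified by magic
  rec <- generate_ecg("NORM", clean_synth_config(), seed = 1)
  noext <- file.path(d, "blob")
  ecgtune:::npy_write(rec$signal, noext)
  expect_equal(sniff_format(noext), "npy")

  # random bytes are rejected
  bin <- file.path(d, "x.bin")
  writeBin(as.raw(c(1, 2, 3, 254, 250, 128, 7, 9)), bin)
  expect_error(sniff_format(bin), class = "UnsupportedFormat")
  expect_error(sniff_format(file.path(d, "ghost.csv")), class = "ReadError")
})

test_that("write -> read round-trips reproduce the signal", {
  d <- withr::local_tempdir()
  rec <- generate_ecg("NORM", clean_synth_config(), seed = 3)
  for (fmt in c("csv", "npy")) {
    p <- file.path(d, paste0("rt.", fmt))
    write_ecg(rec, p, fmt)
    back <- read_ecg(p, fs = rec$fs)
    expect_lt(max(abs(back$signal - rec$signal)), 1e-6)
    expect_equal(dim(back$signal), dim(rec$signal))
  }
  # DAT quantizes at the declared gain: half-ulp of 1/1000 mV
  p <- file.path(d, "rt.hea")
  write_ecg(rec, p, "dat")
  back <- read_ecg(p)
  expect_lte(max(abs(back$signal - rec$signal)), 0.0005 + 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$lead_names, rec$lead_names)
})

test_that("the same waveform agrees across csv, npy and dat containers", {
  d <- withr::local_tempdir()
  rec <- generate_ecg("STSHIFT", clean_synth_config(), seed = 9)
  sigs <- lapply(c("csv", "npy", "dat"), function(fmt) {
    p <- file.path(d, paste0("eq_", fmt, ".", if (fmt == "dat") "hea" else fmt))
    write_ecg(rec, p, fmt)
    read_ecg(p, fs = rec$fs)$signal
  })
  expect_lt(max(abs(sigs[[1]] - sigs[[2]])), 1e-3)
  expect_lt(max(abs(sigs[[1]] - sigs[[3]])), 1e-3)
})

test_that("declared container gain is divided out (v/g mV)", {
  d <- withr::local_tempdir()
  for (g in c(200, 1000)) {
    # store the integer value equal to the gain -> exactly 1.0 mV
    rec <- ecg_record(matrix(1, 2, 50), fs = 500, lead_names = c("I", "II"),
                      gain_adu_per_mv = g)
    p <- file.path(d, sprintf("g%d.hea", g))
    ecgtune:::wfdb_write(rec, p, gain = g)
    back <- read_ecg(p)
    expect_equal(unname(back$signal[1, 1]), 1.0)
    expect_equal(back$gain_adu_per_mv, g)
  }
})

test_that("orientation is resolved with the <= 16 leads rule", {
  d <- withr::local_tempdir()
  sig <- matrix(rnorm(12 * 500), 12)
  p1 <- file.path(d, "wide.npy"); p2 <- file.path(d, "tall.npy")
  ecgtune:::npy_write(sig, p1)        # 12 x 500
  ecgtune:::npy_write(t(sig), p2)     # 500 x 12
  a <- read_ecg(p1, fs = 100); b <- read_ecg(p2, fs = 100)
  expect_equal(a$signal, b$signal)
})

test_that("missing sampling metadata errors instead of guessing", {
  d <- withr::local_tempdir()
  p <- file.path(d, "nofs.csv")
  write_ecg(generate_ecg("NORM", clean_synth_config(), seed = 2), p, "csv")
  expect_error(read_ecg(p), class = "MissingMetadata")
  expect_s3_class(read_ecg(p, fs = 100), "ecg_record")
})

test_that("NPZ archives and non-numeric payloads are handled", {
  d <- withr::local_tempdir()
  sig <- matrix(rnorm(4 * 30), 4)
  npy <- file.path(d, "arr.npy")
  ecgtune:::npy_write(sig, npy)
  npz <- file.path(d, "arr.npz")
  write_stored_zip(npz, "arr.npy", readBin(npy, "raw", file.size(npy)))
  expect_equal(read_ecg(npz, fs = 100)$signal, sig, tolerance = 1e-12)

  bad <- file.path(d, "bad.csv")
  writeLines(c("I,II", "0.1,0.2", "oops,0.3"), bad)
  expect_error(read_ecg(bad, fs = 100), class = "ReadError")
})

test_that("DICOM waveform fixtures read back with sensitivity applied", {
  d <- withr::local_tempdir()
  adu <- matrix(c(200L, -100L, 0L, 50L, 400L, -400L), nrow = 2) # 2 ch x 3 samp
  p <- file.path(d, "wave.dcm")
  write_dicom_fixture(p, adu, fs = 500, sensitivity = 1 / 200,
                      labels = c("I", "II"))
  rec <- read_ecg(p)
  expect_equal(rec$fs, 500)
  expect_equal(rec$lead_names, c("I", "II"))
  expect_equal(rec$signal, adu / 200, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rec$gain_adu_per_mv, 200)
})

test_that("MAT files honor fs/gain variables and pick the signal matrix", {
  d <- withr::local_tempdir()
  sig_adu <- matrix(round(rnorm(3 * 40) * 100), 3)
  p <- file.path(d, "ecg.mat")
  write_mat_fixture(p, list(fs = matrix(250), gain = matrix(100),
                            ecg = sig_adu))
  rec <- read_ecg(p)
  expect_equal(rec$fs, 250)
  expect_equal(rec$signal, sig_adu / 100, tolerance = 1e-12, ignore_attr = TRUE)

  # without fs the reader demands an override
  p2 <- file.path(d, "bare.mat")
  write_mat_fixture(p2, list(x = sig_adu))
  expect_error(read_ecg(p2), class = "MissingMetadata")
  expect_equal(read_ecg(p2, fs = 100)$fs, 100)
})

test_that("the generic XML dialect round-trips", {
  d <- withr::local_tempdir()
  rec <- generate_ecg("WIDE", clean_synth_config(fs = 250), seed = 4)
  p <- file.path(d, "rec.xml")
  ecgtune:::xmlecg_write(rec, p, gain = 1000)
  back <- read_ecg(p)
  expect_equal(back$fs, 250)
  expect_equal(back$lead_names, rec$lead_names)
  expect_lt(max(abs(back$signal - rec$signal)), 0.0005 + 1e-12)
})

test_that("manifests are validated and carry a sorted vocabulary", {
  d <- withr::local_tempdir()
  p <- file.path(d, "manifest.csv")
  utils::write.csv(data.frame(record_path = c("a.npy", "b.npy", "c.npy"),
                              patient_id = c("p1", "p2", "p1"),
                              label = c("B", "A", "B")),
                   p, row.names = FALSE)
  man <- read_manifest(p)
  expect_equal(nrow(man), 3)
  expect_equal(attr(man, "classes"), c("A", "B"))

  utils::write.csv(data.frame(record_path = c("a.npy", "a.npy"),
                              patient_id = c("p1", "p2"), label = c("A", "B")),
                   p, row.names = FALSE)
  expect_error(read_manifest(p), class = "ManifestError")

  utils::write.csv(data.frame(record_path = "a.npy", patient_id = "p1"),
                   p, row.names = FALSE)
  expect_error(read_manifest(p), class = "ManifestError")

  writeLines("record_path,patient_id,label", p)
  expect_error(read_manifest(p), class = "ManifestError")
})
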