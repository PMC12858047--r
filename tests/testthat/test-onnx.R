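test_that("export -> import preserves the forward pass", {
  d <- withr::local_tempdir()
  for (arch in c("xceptiontime", "inceptiontime")) {
    m <- build_model(tiny_spec(arch, K = 3), seed = 14)
    f <- file.path(d, paste0(arch, ".onnx"))
    export_model(m, f)
    m2 <- import_model(f)
    expect_equal(m2$spec$n_classes, 3L)
    expect_equal(m2$spec$in_channels, 2L)
    expect_equal(m2$head, m$head)
    expect_lte(m2$meta$source_opset, 20)
    set.seed(1)
    x <- array(rnorm(10 * 2 * 32), c(10, 2, 32))
    expect_lt(max(abs(model_forward(m, x)$logits - model_forward(m2, x)$logits)),
              1e-4)
  }
})

test_that("re-export of an imported model is byte-stable", {
  d <- withr::local_tempdir()
  m <- build_model(tiny_spec("xceptiontime", K = 2), seed = 3)
  f1 <- file.path(d, "a.onnx"); f2 <- file.path(d, "b.onnx")
  export_model(m, f1)
  export_model(import_model(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("corrupt files and high opsets are rejected", {
  d <- withr::local_tempdir()
  trunc <- file.path(d, "trunc.onnx")
  writeBin(as.raw(c(8, 8, 18)), trunc) # dangling length-delimited field
  expect_error(import_model(trunc), class = "ConversionError")

  # craft a minimal model declaring Opset 21
  m <- build_model(tiny_spec(K = 2), seed = 1)
  raw <- ecgtune:::onnx_serialize_model(m)
  patched <- ecgtune:::pb_cat(
    raw[seq_len(length(raw) - length(ecgtune:::pb_bytes(8, ecgtune:::pb_int(2, 17))))],
    ecgtune:::pb_bytes(8, ecgtune:::pb_int(2, 21)))
  high <- file.path(d, "high.onnx")
  writeBin(patched, high)
  expect_error(import_model(high), class = "UnsupportedOpset")
})

test_that("head adaptation replaces exactly one parameter group", {
  d <- withr::local_tempdir()
  # imported many-class model adapted down to 5 classes
  wide <- build_model(model_spec("inceptiontime", in_channels = 2,
                                 n_samples = 32, n_classes = 26, nf = 2),
                      seed = 8)
  f <- file.path(d, "wide.onnx")
  export_model(wide, f)
  imp <- import_model(f)
  before <- ecgtune:::model_checksums(imp)
  adapted <- adapt_head(imp, 5, seed = 4)
  after <- ecgtune:::model_checksums(adapted)
  expect_equal(adapted$spec$n_classes, 5L)
  changed <- names(before)[abs(before - after) > 0]
  expect_identical(changed, adapted$head)
  x <- array(rnorm(3 * 2 * 32), c(3, 2, 32))
  expect_equal(dim(model_forward(adapted, x)$logits), c(3L, 5L))

  # width-preserving adaptation still re-initializes the head
  same <- adapt_head(imp, 26, seed = 9)
  cs <- ecgtune:::model_checksums(same)
  expect_false(isTRUE(all.equal(before[[imp$head]], cs[[imp$head]])))
  expect_identical(before[setdiff(names(before), imp$head)],
                   cs[setdiff(names(cs), imp$head)])
})

test_that("graphs without an affine head raise HeadNotFound", {
  # hand-built graph: conv(k=3) -> relu -> gap; no affine map anywhere
  gb <- ecgtune:::gb_new(model_spec("inceptiontime", in_channels = 2,
                                    n_samples = 16, n_classes = 2, nf = 2))
  c1 <- ecgtune:::gb_conv(gb, "c1", "input", 2L, 4L, 3L)
  r1 <- ecgtune:::gb_add(gb, "r1", "relu", c1)
  ecgtune:::gb_add(gb, "g", "gap", r1)
  m <- ecgtune:::finish_model(gb, output = "g", head = NULL)
  d <- withr::local_tempdir()
  f <- file.path(d, "headless.onnx")
  export_model(m, f)
  expect_error(import_model(f), class = "HeadNotFound")
  expect_error(adapt_head(m, 3), class = "HeadNotFound")
})

test_that("freezing strategies set trainable counts and are idempotent", {
  m <- build_model(model_spec("xceptiontime", n_classes = 5), seed = 2)
  total <- count_parameters(m)
  head_n <- sum(vapply(m$params[[m$head]], length, integer(1)))
  mh <- set_strategy(m, "head")
  expect_equal(count_parameters(mh), head_n)
  expect_equal(count_parameters(mh), 128 * 5 + 5)
  mf <- set_strategy(mh, "full")
  expect_equal(count_parameters(mf), total)
  expect_equal(count_parameters(set_strategy(set_strategy(mf, "head"), "head")),
               head_n)
})

test_that("exports run at any batch size (dynamic batch contract)", {
  d <- withr::local_tempdir()
  m <- build_model(tiny_spec("xceptiontime", K = 4), seed = 5)
  f <- file.path(d, "dyn.onnx")
  export_model(m, f)
  m2 <- import_model(f)
  for (n in c(1L, 7L)) {
    x <- array(rnorm(n * 2 * 32), c(n, 2, 32))
    expect_equal(dim(model_forward(m2, x)$logits), c(n, 4L))
  }
})
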