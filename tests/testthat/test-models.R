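test_that("default architectures reproduce the published complexity figures", {
  mx <- build_model(model_spec("xceptiontime", n_classes = 5))
  mi <- build_model(model_spec("inceptiontime", n_classes = 5))
  # parameter counts, rounded to the nearest thousand
  expect_equal(round(count_parameters(mx) / 1000), 401)
  expect_lte(abs(count_parameters(mi) / 1000 - 457), 1)
  # forward-pass MACs on a 12 x 1000 input, MAC-as-one-FLOP convention
  expect_lt(abs(count_flops(mx) / 1e6 - 256) / 256, 0.02)
  expect_lt(abs(count_flops(mi) / 1e6 - 460) / 460, 0.02)
})

test_that("forward pass is finite and respects the batch shape contract", {
  for (arch in c("xceptiontime", "inceptiontime")) {
    m <- build_model(tiny_spec(arch, K = 3L), seed = 5)
    for (n in c(1L, 2L, 17L)) {
      x <- array(rnorm(n * 2 * 32), c(n, 2L, 32L))
      logits <- model_forward(m, x)$logits
      expect_equal(dim(logits), c(n, 3L))
      expect_true(all(is.finite(logits)))
    }
    # zero input also yields finite logits
    z <- model_forward(m, array(0, c(1, 2, 32)))$logits
    expect_true(all(is.finite(z)))
  }
})

test_that("builds are deterministic given spec and seed", {
  for (arch in c("xceptiontime", "inceptiontime")) {
    a <- build_model(model_spec(arch, n_classes = 4), seed = 9)
    b <- build_model(model_spec(arch, n_classes = 4), seed = 9)
    expect_identical(ecgtune:::model_checksums(a), ecgtune:::model_checksums(b))
    d <- build_model(model_spec(arch, n_classes = 4), seed = 10)
    expect_false(isTRUE(all.equal(ecgtune:::model_checksums(a),
                                  ecgtune:::model_checksums(d))))
  }
})

test_that("FLOP accounting follows the stated conventions", {
  m <- build_model(tiny_spec("inceptiontime"), seed = 1)
  sh <- ecgtune:::shape_trace(m)
  # manual recount from the graph: conv = Cin*k*Cout*L, linear = in*out
  manual <- 0
  for (node in m$nodes) {
    a <- node$attrs
    manual <- manual + switch(node$op,
      conv = a$in_ch * a$k * a$out_ch * sh[[node$id]][["L"]],
      dwconv = a$ch * a$k * sh[[node$id]][["L"]],
      linear = a$d_in * a$d_out,
      0)
  }
  expect_equal(count_flops(m), manual)
})

test_that("executor gradients agree with finite differences on tiny models", {
  loss_of <- function(m, x, y, w) {
    ecgtune:::nn_train_batch(m, x, y, w, training = TRUE)$loss
  }
  for (arch in c("xceptiontime", "inceptiontime")) {
    spec <- model_spec(arch, in_channels = 2, n_samples = 16, n_classes = 2, nf = 2)
    m <- build_model(spec, seed = 3)
    set.seed(11)
    x <- array(rnorm(3 * 2 * 16), c(3, 2, 16))
    y <- c(1L, 2L, 1L); w <- c(0.7, 1.3)
    fw <- ecgtune:::nn_train_batch(m, x, y, w, training = TRUE)
    checked <- 0L
    set.seed(12)
    for (id in sample(names(fw$grads), 8)) {
      for (nm in names(fw$grads[[id]])) {
        g <- fw$grads[[id]][[nm]]
        if (is.null(g) || !length(g)) next
        i <- which.max(abs(g)) # float32 finite differences need a large signal
        eps <- 5e-3
        m2 <- m
        m2$params[[id]][[nm]][i] <- m2$params[[id]][[nm]][i] + eps
        l1 <- loss_of(m2, x, y, w)
        m2$params[[id]][[nm]][i] <- m2$params[[id]][[nm]][i] - 2 * eps
        l2 <- loss_of(m2, x, y, w)
        num <- (l1 - l2) / (2 * eps)
        if (abs(num) > 2e-2) {
          # tolerance accommodates max-pool/ReLU kinks crossed by the step
          expect_lt(abs(num - g[i]) / (abs(num) + abs(g[i])), 0.08)
          checked <- checked + 1L
        }
      }
    }
    expect_gte(checked, 5L)
  }
})

test_that("training-mode forward updates batch-norm running statistics", {
  m <- build_model(tiny_spec(), seed = 2)
  x <- array(rnorm(4 * 2 * 32, mean = 3), c(4, 2, 32))
  before <- m$state
  after <- model_forward(m, x, training = TRUE)$model$state
  bn_id <- names(before)[1]
  expect_false(isTRUE(all.equal(before[[bn_id]]$rmean, after[[bn_id]]$rmean)))
  # inference-mode forward leaves them untouched
  same <- model_forward(m, x, training = FALSE)$model$state
  expect_identical(before, same)
})
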