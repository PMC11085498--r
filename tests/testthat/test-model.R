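# Network operations against loop oracles, the residual-block contracts and
# the architecture audit.

test_that("ECA kernel size follows the nearest-odd rule", {
  expect_identical(eca_kernel_size(512), 5L)
  expect_identical(eca_kernel_size(1), 1L)
  expect_identical(eca_kernel_size(64), 3L)   # 3.5 ties down to 3
  expect_identical(eca_kernel_size(32), 3L)
  expect_identical(eca_kernel_size(256), 5L)  # 4.5 -> nearest odd 5
  for (C in c(1:16, 32, 64, 128, 256, 512, 1024)) {
    k <- eca_kernel_size(C)
    expect_identical(k %% 2L, 1L)
    expect_gte(k, 1L)
  }
  expect_error(eca_kernel_size(0), "positive")
})

test_that("global average pooling matches a triple-loop oracle", {
  cmap <- array(3, c(4, 5, 2))
  expect_equal(global_average_pool(cmap), c(3, 3))
  expect_equal(global_average_pool(array(c(1, 3, 2, 4), c(2, 2, 1))), 2.5)
  set.seed(17)
  fm <- array(rnorm(7 * 5 * 16), c(7, 5, 16))
  expect_equal(global_average_pool(fm), naive_gap(fm), tolerance = 1e-12)
  # batched form agrees column-wise
  fmb <- array(rnorm(7 * 5 * 16 * 3), c(7, 5, 16, 3))
  g <- global_average_pool(fmb)
  for (n in 1:3) expect_equal(g[, n], naive_gap(fmb[, , , n]), tolerance = 1e-12)
  expect_error(global_average_pool(matrix(1, 2, 2)), "array")
})

test_that("ECA attention matches the sliding-dot-product oracle and stays in (0,1)", {
  # zero kernel: sigmoid(0) = 0.5 everywhere, attended = pooled / 2
  sp <- eca_spec(16)
  set.seed(2)
  p <- rnorm(16)
  r <- eca_attend(p, sp)
  expect_equal(r$weights, rep(0.5, 16))
  expect_equal(r$attended, p / 2)

  for (i in 1:25) {
    C <- sample(c(8, 16, 32, 64, 128, 256, 512), 1)
    sp <- eca_spec(C, conv_weights = rnorm(eca_kernel_size(C)))
    p <- rnorm(C) * 3
    r <- eca_attend(p, sp)
    o <- naive_eca(p, sp$conv_weights)
    expect_lt(max(abs(r$weights - o$weights)), 1e-6)
    expect_lt(max(abs(r$attended - o$attended)), 1e-6)
    expect_true(all(r$weights > 0 & r$weights < 1))
    expect_true(all(abs(r$attended) <= abs(p)))
  }
  expect_error(eca_attend(rnorm(8), eca_spec(16)), "channels")
  expect_error(eca_spec(16, conv_weights = rnorm(4)), "length")
})

test_that("a zero residual path makes the block an identity on nonnegative input", {
  spec <- residual_block_spec(4, 4, stride = 1)
  expect_false(spec$projection)
  set.seed(3)
  x <- abs(array(rnorm(6 * 8 * 4), c(6, 8, 4)))
  y <- residual_block_forward(x, spec)  # default params: zero residual path
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("residual block agrees with a naive convolution oracle", {
  spec <- residual_block_spec(4, 6, stride = 2)
  expect_true(spec$projection)
  set.seed(9)
  params <- emgfuse:::residual_block_params(spec)
  params$conv1 <- array(rnorm(3 * 3 * 4 * 6, sd = 0.3), c(3, 3, 4, 6))
  params$conv2 <- array(rnorm(3 * 3 * 6 * 6, sd = 0.3), c(3, 3, 6, 6))
  params$proj <- array(rnorm(1 * 1 * 4 * 6, sd = 0.3), c(1, 1, 4, 6))
  for (bn in c("bn1", "bn2", "proj_bn")) {
    params[[bn]]$gamma <- runif(6, 0.5, 1.5)
    params[[bn]]$beta <- rnorm(6, sd = 0.2)
    params[[bn]]$mean <- rnorm(6, sd = 0.2)
    params[[bn]]$var <- runif(6, 0.5, 2)
  }
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- residual_block_forward(x, spec, params)

  f <- naive_conv2d(x, params$conv1, stride = c(2, 2))
  f <- naive_bn(f, params$bn1$gamma, params$bn1$beta, params$bn1$mean, params$bn1$var)
  f <- pmax(f, 0)
  f <- naive_conv2d(f, params$conv2)
  f <- naive_bn(f, params$bn2$gamma, params$bn2$beta, params$bn2$mean, params$bn2$var)
  sc <- naive_conv2d(x, params$proj, stride = c(2, 2), pad = c(0, 0))
  sc <- naive_bn(sc, params$proj_bn$gamma, params$proj_bn$beta,
                 params$proj_bn$mean, params$proj_bn$var)
  expect_lt(max(abs(y - pmax(f + sc, 0))), 1e-5)

  # stride-2 56x56 input, 64 -> 128 channels: output halves to 28x28
  spec2 <- residual_block_spec(64, 128, stride = 2)
  x2 <- array(0, c(56, 56, 64))
  expect_identical(dim(residual_block_forward(x2, spec2)), c(28L, 28L, 128L))
})

test_that("with a null residual path the block's input gradient is the identity", {
  # the shortcut contributes a constant +1 to dy/dx, so at zero residual
  # weights the Jacobian (on strictly positive input) is exactly identity
  spec <- residual_block_spec(2, 2, stride = 1)
  set.seed(5)
  x0 <- abs(array(rnorm(3 * 4 * 2), c(3, 4, 2))) + 0.5
  f <- function(xv) as.vector(residual_block_forward(array(xv, dim(x0)), spec))
  eps <- 1e-6
  n <- length(x0)
  probe <- sample(n, 8)
  for (i in probe) {
    xp <- as.vector(x0); xm <- as.vector(x0)
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g <- (f(xp) - f(xm)) / (2 * eps)
    expected <- numeric(n); expected[i] <- 1
    expect_lt(max(abs(g - expected)), 1e-6)
  }
})

test_that("branch presets emit the documented feature lengths", {
  sm <- build_branch(branch_spec(c(12, 100, 1), "small"), seed = 1)
  x <- array(rnorm(12 * 100 * 1 * 3), c(12, 100, 1, 3))
  v <- sm$fwd(x)
  expect_identical(dim(v), c(32L, 3L))

  fl <- build_branch(branch_spec(c(12, 400, 1), "full"), seed = 1)
  xf <- array(rnorm(12 * 400 * 1 * 2), c(12, 400, 1, 2))
  vf <- fl$fwd(xf)
  expect_identical(dim(vf), c(512L, 2L))

  # batching is order-preserving
  v1 <- sm$fwd(x[, , , 1, drop = FALSE])
  expect_equal(v[, 1], v1[, 1], tolerance = 1e-10)
})

test_that("the full preset reproduces the classical stage sizes on a 224x224 probe", {
  br <- build_branch(branch_spec(c(224, 224, 1), "full"), seed = 1)
  sizes <- branch_stage_sizes(br, c(224, 224, 1))
  expect_equal(unname(sizes[, "rows"]), c(56, 28, 14, 7))
  expect_equal(unname(sizes[, "cols"]), c(56, 28, 14, 7))
})

test_that("the two-stream model fuses branch features and emits probabilities", {
  spec <- two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 5, preset = "small")
  expect_identical(spec$fused_dim, 64L)
  # full preset fuses two 512-vectors
  expect_identical(two_stream_spec(n_classes = 49, preset = "full")$fused_dim, 1024L)

  m <- build_two_stream(spec, seed = 2)
  set.seed(11)
  emg <- array(rnorm(12 * 40 * 4), c(12, 40, 4))
  acc <- array(rnorm(36 * 40 * 4), c(36, 40, 4))
  p <- model_forward(m, emg, acc)
  expect_identical(dim(p), c(5L, 4L))
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0))

  # inference is deterministic (dropout off)
  expect_identical(p, model_forward(m, emg, acc))

  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  p2 <- model_forward(m, emg[, , perm], acc[, , perm])
  expect_equal(p2, p[, perm], tolerance = 1e-10)

  # zero-initialized head gives uniform probabilities
  m$fc2$params$W[] <- 0
  m$fc2$params$b[] <- 0
  pu <- model_forward(m, emg, acc)
  expect_equal(as.vector(pu), rep(1 / 5, 20), tolerance = 1e-12)

  expect_error(model_forward(m, emg, acc[, , 1:3]), "different sizes")
  expect_error(two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 1), "n_classes")
})

test_that("checkpoints restore an identical inference model", {
  spec <- two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 3, preset = "small")
  m <- build_two_stream(spec, seed = 4)
  m$classes <- c(1L, 2L, 3L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  set.seed(6)
  emg <- array(rnorm(12 * 40 * 2), c(12, 40, 2))
  acc <- array(rnorm(36 * 40 * 2), c(36, 40, 2))
  expect_identical(model_forward(m, emg, acc), model_forward(m2, emg, acc))
  expect_identical(m2$classes, m$classes)
})
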