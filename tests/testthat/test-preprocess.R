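# Filtering, normalization and segmentation against frequency-response and
# loop oracles.

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  spec <- filter_spec()

  # in-band: 100 Hz unit sinusoid passes with < 5% amplitude error
  x <- matrix(sin(2 * pi * 100 * t), ncol = 1)
  y <- bandpass_filter(x, spec, fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- max(abs(y[mid, 1]))
  expect_lt(abs(amp - 1), 0.05)

  # out-of-band: 1 Hz unit sinusoid is strongly attenuated
  x1 <- matrix(sin(2 * pi * 1 * t), ncol = 1)
  y1 <- bandpass_filter(x1, spec, fs)
  expect_lt(max(abs(y1[mid, 1])), 0.1)

  # linearity: filter(a + b) == filter(a) + filter(b)
  set.seed(12)
  a <- matrix(rnorm(3000 * 2), 3000, 2)
  b <- matrix(rnorm(3000 * 2), 3000, 2)
  expect_equal(bandpass_filter(a + b, spec, fs),
               bandpass_filter(a, spec, fs) + bandpass_filter(b, spec, fs),
               tolerance = 1e-9)

  # band edge at/above Nyquist is rejected
  expect_error(bandpass_filter(a, spec, fs = 500), "Nyquist")
})

test_that("normalizer statistics match a per-channel loop oracle", {
  expect_equal(unclass(fit_normalizer(matrix(c(1, 3), ncol = 1)))[c("mean", "std")],
               list(mean = 2, std = 1))
  expect_error(fit_normalizer(cbind(rnorm(50), rep(2, 50))), "channel 2")

  set.seed(4)
  x <- matrix(rnorm(1000 * 12, mean = 3, sd = 2), 1000, 12)
  st <- fit_normalizer(x)
  for (ch in 1:12) {
    mu <- sum(x[, ch]) / 1000
    expect_equal(st$mean[ch], mu, tolerance = 1e-12)
    expect_equal(st$std[ch], sqrt(sum((x[, ch] - mu)^2) / 1000), tolerance = 1e-12)
  }
})

test_that("fit-then-apply standardizes and the transform is invertible", {
  set.seed(8)
  x <- matrix(rnorm(5000 * 12, mean = -2, sd = 5), 5000, 12)
  st <- fit_normalizer(x)
  y <- apply_normalizer(x, st)
  m2 <- colMeans(y)
  s2 <- sqrt(colMeans(y^2) - m2^2)
  expect_true(all(abs(m2) < 1e-8))
  expect_true(all(abs(s2 - 1) < 1e-6))
  expect_equal(invert_normalizer(y, st), x, tolerance = 1e-9)

  # already standardized input is (numerically) unchanged
  y2 <- apply_normalizer(y, fit_normalizer(y))
  expect_equal(y2, y, tolerance = 1e-6)
  # constant input at the channel means maps to all zeros
  at_mu <- matrix(st$mean, nrow = 7, ncol = 12, byrow = TRUE)
  expect_true(all(abs(apply_normalizer(at_mu, st)) < 1e-12))
  expect_error(apply_normalizer(x[, 1:5], st), "mismatch")
})

test_that("window arithmetic converts ms to samples exactly", {
  ws <- window_spec(200, 50, 2000)
  expect_identical(c(ws$L, ws$Ld), c(400L, 100L))
  for (T_ms in c(100, 150, 250)) {
    ws <- window_spec(T_ms, 50, 2000)
    expect_identical(ws$L, as.integer(T_ms * 2))
    expect_identical(ws$Ld, 100L)
  }
  expect_identical(window_spec(200, 50, 500)$L, 100L)
  expect_error(window_spec(200.25, 50, 2000), "whole")
})

test_that("segmentation emits floor((n - L)/Ld) + 1 windows of contiguous slices", {
  spec <- window_spec(200, 50, 2000)  # L = 400, Ld = 100
  set.seed(21)
  x <- matrix(rnorm(10000 * 3), 10000, 3)
  ws <- segment_windows(x, rep(2L, 10000), spec)
  expect_identical(ws$n_windows, 97L)
  expect_identical(ws$n_windows, naive_window_count(10000, 400, 100))
  expect_true(all(ws$labels == 2L))
  # windows are exact contiguous transposed slices
  for (k in c(1, 50, 97)) {
    off <- (k - 1) * 100
    expect_equal(ws$x[, , k], t(x[(off + 1):(off + 400), ]))
  }
  # degenerate: shorter than one window
  expect_warning(ws0 <- segment_windows(x[1:399, ], rep(1L, 399), spec), "shorter")
  expect_identical(ws0$n_windows, 0L)
})

test_that("window-count law holds across random stream lengths", {
  spec <- window_spec(200, 50, 2000)
  set.seed(33)
  for (n in sample(400:20000, 25)) {
    x <- matrix(0, n, 1)
    ws <- suppressWarnings(segment_windows(x, rep(1L, n), spec))
    expect_identical(ws$n_windows, naive_window_count(n, spec$L, spec$Ld))
  }
})

test_that("window labeling follows the majority/strict policies", {
  spec <- window_spec(T_ms = 20, S_ms = 20, fs_hz = 500)  # L = Ld = 10
  x <- matrix(0, 30, 2)
  # window 2 mixes rest and movement -> dropped under majority
  labels <- c(rep(1L, 10), rep(1L, 4), rep(0L, 6), rep(2L, 10))
  ws <- segment_windows(x, labels, spec)
  expect_identical(ws$labels, c(1L, 2L))
  # movement-movement mixture keeps the majority label
  labels2 <- c(rep(1L, 10), rep(1L, 4), rep(2L, 6), rep(2L, 10))
  ws2 <- segment_windows(x, labels2, spec)
  expect_identical(ws2$labels, c(1L, 2L, 2L))
  # ties go to the lower label
  labels3 <- c(rep(1L, 5), rep(2L, 5), rep(3L, 20))
  expect_identical(segment_windows(x, labels3, spec)$labels, c(1L, 3L, 3L))
  # strict drops every mixed window
  expect_identical(segment_windows(x, labels2, spec, labeling = "strict")$labels,
                   c(1L, 2L))
})

test_that("full chain yields aligned EMG/ACC pairs and leak-free statistics", {
  s <- generate_session(quick_config(), "S1")
  pp <- suppressMessages(preprocess_session(s, window = window_spec(100, 50, 500)))
  expect_identical(pp$train$emg$n_windows, pp$train$acc$n_windows)
  expect_identical(pp$train$emg$labels, pp$train$acc$labels)
  expect_identical(pp$test$emg$labels, pp$test$acc$labels)
  expect_gt(pp$train$emg$n_windows, 0L)
  expect_gt(pp$test$emg$n_windows, 0L)
  # train windows come only from train repetitions (labels never rest)
  expect_true(all(pp$train$labels > 0))
  # stats fitted on train samples only: refit on the train mask reproduces them
  fs <- s$sampling_rate_hz
  filt <- filter_spec(4, c(10, 0.45 * fs))
  emg_f <- bandpass_filter(s$emg, filt, fs)
  masks <- split_by_repetition(s)
  st <- fit_normalizer(emg_f[masks$train, ])
  expect_equal(st$mean, pp$stats$emg$mean, tolerance = 1e-12)
  expect_equal(st$std, pp$stats$emg$std, tolerance = 1e-12)
})
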