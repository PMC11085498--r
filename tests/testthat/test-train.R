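# Loss closed forms, validation split, the plateau schedule and optimizer
# behavior.

test_that("cross-entropy matches its closed forms and a loop oracle", {
  # perfect one-hot prediction -> 0
  y <- diag(4)
  expect_equal(cross_entropy_loss(y, y), 0, tolerance = 1e-10)
  # uniform prediction over 50 classes -> ln 50
  yt <- matrix(0, 6, 50); yt[cbind(1:6, sample(50, 6))] <- 1
  yp <- matrix(1 / 50, 6, 50)
  expect_equal(cross_entropy_loss(yt, yp), log(50), tolerance = 1e-12)

  set.seed(14)
  n <- 40; k <- 7
  yt <- matrix(0, n, k); yt[cbind(1:n, sample(k, n, replace = TRUE))] <- 1
  raw <- matrix(rexp(n * k), n, k)
  yp <- raw / rowSums(raw)
  expect_equal(cross_entropy_loss(yt, yp), naive_cross_entropy(yt, yp),
               tolerance = 1e-10)

  expect_error(cross_entropy_loss(yt, yp[, 1:3]), "shape")
  expect_error(cross_entropy_loss(yt, raw), "sum to 1")
})

test_that("validation split is stratified, disjoint and pairing-preserving", {
  set.seed(20)
  n <- 1000
  labels <- rep(1:5, each = 200)
  x <- array(rnorm(12 * 10 * n), c(12, 10, n))
  x[1, 1, ] <- seq_len(n)  # marker to track pairing
  a <- array(rnorm(36 * 10 * n), c(36, 10, n))
  a[1, 1, ] <- seq_len(n)
  data <- list(labels = labels, emg = window_set(x, labels, "emg"),
               acc = window_set(a, labels, "acc"))
  parts <- split_validation(data, 0.1, seed = 3)
  expect_identical(length(parts$val$labels), 100L)
  expect_identical(length(parts$train$labels), 900L)
  # per-class proportions within one window of fraction * count
  for (k in 1:5)
    expect_lte(abs(sum(parts$val$labels == k) - 20), 1)
  # disjoint and exhaustive via the marker channel
  tr_ids <- parts$train$emg$x[1, 1, ]
  va_ids <- parts$val$emg$x[1, 1, ]
  expect_identical(sort(c(tr_ids, va_ids)), as.numeric(1:n))
  # EMG/ACC pairing preserved
  expect_identical(parts$train$emg$x[1, 1, ], parts$train$acc$x[1, 1, ])
  expect_identical(parts$val$emg$x[1, 1, ], parts$val$acc$x[1, 1, ])
  # deterministic given the seed
  parts2 <- split_validation(data, 0.1, seed = 3)
  expect_identical(parts$val$labels, parts2$val$labels)
  # fraction 0: empty validation part
  expect_identical(length(split_validation(data, 0, seed = 1)$val$labels), 0L)
})

test_that("the plateau schedule yields lr = initial * factor^drops", {
  sch <- plateau_scheduler(0.001, factor = 0.1, patience = 1, min_lr = 1e-6)
  # constructed monitor sequence: improve, plateau, improve, plateau, plateau
  seqv <- c(1.0, 1.1, 0.8, 0.9, 0.95, 0.7, 0.9)
  lrs <- numeric(length(seqv))
  for (i in seq_along(seqv)) {
    sch <- scheduler_step(sch, seqv[i])
    lrs[i] <- sch$lr
  }
  # drops fire exactly when the value fails to improve on the best so far;
  # the 4th drop hits the 1e-6 floor
  expect_equal(lrs, pmax(0.001 * 0.1^c(0, 1, 1, 2, 3, 3, 4), 1e-6))
  expect_identical(sch$drops, 4L)
  expect_equal(sch$lr, 1e-6)
  # floor
  sch2 <- plateau_scheduler(1e-5, factor = 0.1, patience = 1, min_lr = 1e-6)
  sch2 <- scheduler_step(sch2, 1); sch2 <- scheduler_step(sch2, 2)
  sch2 <- scheduler_step(sch2, 3)
  expect_equal(sch2$lr, 1e-6)
  # patience 2 waits two stagnant epochs
  sch3 <- plateau_scheduler(0.001, patience = 2)
  for (v in c(1, 2, 2)) sch3 <- scheduler_step(sch3, v)
  expect_equal(sch3$lr, 1e-4)
  expect_identical(sch3$drops, 1L)
})

test_that("one optimizer step on a frozen batch decreases the loss", {
  dw <- tiny_windows(n_per_class = 24, L = 40)
  spec <- two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 2, preset = "small")
  cfg <- train_config(epochs = 1, batch_size = 48, initial_lr = 1e-4,
                      val_fraction = 0, seed = 2)
  m <- build_two_stream(spec, seed = 2)
  ins <- emgfuse:::.batch_inputs(dw, 1:48)
  yi <- ifelse(dw$labels == 1, 1L, 2L)[1:48]
  loss_of <- function(model) {
    p <- emgfuse:::softmax_cols(model$fwd(ins, training = FALSE))
    mean(-log(pmax(p[cbind(yi, 1:48)], 1e-12)))
  }
  l0 <- loss_of(m)
  fit <- train_model(m, dw, cfg)
  l1 <- loss_of(fit$model)
  expect_lt(l1, l0)
})

test_that("training overfits a small two-class problem and is seed-deterministic", {
  dw <- tiny_windows(n_per_class = 100, L = 40)
  spec <- two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 2, preset = "small")
  cfg <- train_config(epochs = 12, batch_size = 64, val_fraction = 0.1, seed = 9)
  fit <- train_model(spec, dw, cfg)
  expect_gte(tail(fit$history$train_acc, 1), 0.99)
  expect_identical(nrow(fit$history), 12L)
  # learning-rate column only ever holds initial_lr * factor^d values
  d <- round(log(fit$history$lr / cfg$initial_lr) / log(cfg$lr_factor))
  expect_true(all(abs(fit$history$lr - cfg$initial_lr * cfg$lr_factor^d) < 1e-15))
  expect_true(all(diff(fit$history$lr) <= 1e-15))

  # identical seeds and data reproduce the run exactly
  fit2 <- train_model(spec, dw, cfg)
  expect_identical(fit$history, fit2$history)
  ev1 <- evaluate_model(fit$model, dw)
  ev2 <- evaluate_model(fit2$model, dw)
  expect_identical(ev1$pred, ev2$pred)

  # checkpoint restore reproduces inference bit-consistently
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(evaluate_model(m2, dw)$pred, ev1$pred)
})

test_that("degenerate training inputs are rejected with clear messages", {
  dw <- tiny_windows(n_per_class = 5, L = 40)
  one_class <- list(labels = rep(1L, 10),
                    emg = window_set(dw$emg$x, rep(1L, 10), "emg"),
                    acc = window_set(dw$acc$x, rep(1L, 10), "acc"))
  spec <- two_stream_spec(c(12, 40, 1), c(36, 40, 1), n_classes = 2, preset = "small")
  expect_error(train_model(spec, one_class, train_config(epochs = 1)), "2 classes")
  expect_error(train_model(spec, list(labels = integer(0)), train_config()), "empty")
})
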