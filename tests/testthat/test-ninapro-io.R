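# Session container, MAT-dialect round trips and the repetition split.

test_that("sessions round-trip through the DB2 fixture dialect exactly", {
  s <- tiny_session(n = 8000)
  path <- withr::local_tempfile(fileext = ".mat")
  write_fixture(s, path)
  s2 <- read_session(path)
  expect_equal(s2$n_samples, 8000)
  expect_equal(dim(s2$emg), c(8000, 12))
  expect_identical(s2$stimulus, s$stimulus)
  expect_identical(s2$repetition, s$repetition)
  expect_equal(s2$emg, s$emg, tolerance = 1e-12)
  expect_equal(s2$acc, s$acc, tolerance = 1e-12)
  expect_equal(s2$sampling_rate_hz, s$sampling_rate_hz)
  expect_identical(s2$annotation, "corrected")

  # distinct subjects give distinct files, both faithful field by field
  sb <- tiny_session(n = 300, subject_id = "S7", seed = 100)
  sc <- tiny_session(n = 300, subject_id = "S8", seed = 100)
  pb <- withr::local_tempfile(fileext = ".mat")
  pc <- withr::local_tempfile(fileext = ".mat")
  write_fixture(sb, pb); write_fixture(sc, pc)
  rb <- read_session(pb); rc <- read_session(pc)
  expect_identical(rb$subject_id, "S7")
  expect_identical(rc$subject_id, "S8")
  for (f in c("emg", "acc", "stimulus", "repetition"))
    expect_equal(rb[[f]], rc[[f]], tolerance = 1e-12)
})

test_that("missing fields and invalid annotations are rejected", {
  path <- withr::local_tempfile(fileext = ".mat")
  s <- tiny_session(n = 200)
  write_mat(list(emg = s$emg, stimulus = as.matrix(s$stimulus),
                 repetition = as.matrix(s$repetition)), path)
  expect_error(read_session(path), "acc")

  write_mat(list(emg = s$emg, acc = s$acc,
                 repetition = as.matrix(s$repetition)), path)
  expect_error(read_session(path), "stimulus")

  # out-of-range gesture label caught by the validator
  bad <- s
  bad$stimulus[5] <- 50L
  write_mat(list(emg = bad$emg, acc = bad$acc,
                 stimulus = as.matrix(bad$stimulus),
                 repetition = as.matrix(bad$repetition)), path)
  expect_error(read_session(path), "stimulus")

  expect_error(recording_session(s$emg[0, , drop = FALSE], s$acc[0, , drop = FALSE],
                                 integer(0), integer(0)), "samples")
  expect_error(recording_session(s$emg, s$acc[-1, ], s$stimulus, s$repetition),
               "mismatch")
})

test_that("the fixture dialect is readable by an independent MAT implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  s <- tiny_session(n = 500)
  path <- withr::local_tempfile(fileext = ".mat")
  write_fixture(s, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c("from scipy.io import loadmat", "import numpy as np, sys",
               sprintf("d = loadmat(%s)", deparse(path)),
               "print('%.10f' % float(np.abs(d['emg']).sum()))",
               "print('%.10f' % float(np.abs(d['acc']).sum()))",
               "print(int(d['restimulus'].max()))"), script)
  out <- system2("python", script, stdout = TRUE)
  expect_equal(as.numeric(out[1]), sum(abs(s$emg)), tolerance = 1e-8)
  expect_equal(as.numeric(out[2]), sum(abs(s$acc)), tolerance = 1e-8)
  expect_equal(as.integer(out[3]), max(s$stimulus))
})

test_that("repetition split matches direct set membership and excludes rest", {
  reps <- c(1L, 1L, 2L, 2L, 5L, 6L)
  s <- tiny_session(n = 6, stimulus = rep(1L, 6), repetition = reps)
  m <- split_by_repetition(s)
  expect_identical(m$train, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(m$test, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))

  expect_error(split_by_repetition(s, train_reps = 1, test_reps = 1), "overlap")

  # brute-force per-sample oracle on a random session
  set.seed(31)
  n <- 4000
  stim <- sample(0:3, n, replace = TRUE)
  rep_idx <- ifelse(stim > 0, sample(1:6, n, replace = TRUE), 0L)
  s <- tiny_session(n = n, stimulus = stim, repetition = rep_idx)
  for (include_rest in c(FALSE, TRUE)) {
    m <- split_by_repetition(s, include_rest = include_rest)
    tr_oracle <- logical(n); te_oracle <- logical(n)
    for (i in seq_len(n)) {
      ok <- include_rest || s$stimulus[i] > 0L
      tr_oracle[i] <- ok && s$repetition[i] %in% c(1, 3, 4, 6)
      te_oracle[i] <- ok && s$repetition[i] %in% c(2, 5)
    }
    expect_identical(m$train, tr_oracle)
    expect_identical(m$test, te_oracle)
    expect_false(any(m$train & m$test))
    if (!include_rest) expect_true(all(s$stimulus[m$train | m$test] > 0))
  }
})
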