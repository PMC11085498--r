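# Small sessions and datasets built in code for the unit tests.

# hand-built session with explicit stimulus/repetition vectors
tiny_session <- function(n = 600, stimulus = NULL, repetition = NULL,
                         fs = 500, seed = 99, subject_id = "T1") {
  set.seed(seed)
  stimulus <- stimulus %||% rep(c(0L, 1L, 2L), length.out = n)
  repetition <- repetition %||% ifelse(stimulus > 0L, 1L, 0L)
  recording_session(matrix(rnorm(n * 12), n, 12),
                    matrix(rnorm(n * 36), n, 36),
                    stimulus, repetition,
                    sampling_rate_hz = fs, subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick synthetic desk session, small enough for fast tests
quick_config <- function(n_classes = 3, reps = 3, movement_s = 0.5,
                         rest_s = 0.25, seed = 7, split_information = FALSE) {
  synthetic_config("desk", n_classes = n_classes, reps = reps,
                   movement_s = movement_s, rest_s = rest_s, seed = seed,
                   split_information = split_information)
}

# tiny paired window dataset for optimizer tests: 2 well-separated classes
tiny_windows <- function(n_per_class = 100, L = 40, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(1:2, each = n_per_class)
  emg <- array(rnorm(12 * L * n, sd = 0.3), c(12, L, n))
  acc <- array(rnorm(36 * L * n, sd = 0.3), c(36, L, n))
  for (i in seq_len(n)) {
    ch <- if (labels[i] == 1) 1:3 else 7:9
    emg[ch, , i] <- emg[ch, , i] + rnorm(3 * L, sd = 1.5)
    acc[ch, , i] <- acc[ch, , i] + sin(2 * pi * (1:L) / 8) * 1.5
  }
  list(labels = labels,
       emg = window_set(emg, labels, "emg"),
       acc = window_set(acc, labels, "acc"))
}
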