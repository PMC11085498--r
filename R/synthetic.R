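# Synthetic multimodal gesture sessions emulating the DB2 recording
# protocol: each movement class is repeated in blocks of `movement_s` seconds
# followed by `rest_s` seconds of rest. EMG is amplitude-modulated
# band-limited Gaussian noise (standard sEMG phenomenology) whose per-channel
# gain encodes the class; ACC is a class-specific sum of low-frequency tones
# (12-40 Hz by default, above the 10 Hz band-pass edge so the class
# information survives filtering) plus Gaussian noise.

#' Configuration for the synthetic session generator
#'
#' The `"full"` preset mirrors the DB2 protocol timing (2000 Hz, 5 s
#' movement + 3 s rest, 6 repetitions); the `"desk"` preset reduces the
#' sampling rate to 500 Hz and the blocks to 2 s movement + 1 s rest so a
#' complete train/evaluate cycle runs on one CPU in minutes while still
#' giving every repetition a useful number of 200 ms windows.
#'
#' @param preset `"full"` or `"desk"`.
#' @param n_classes number of movement classes (default 8).
#' @param n_subjects number of subjects the caller intends to generate.
#' @param fs_hz sampling rate in Hz.
#' @param reps repetitions per class (default 6).
#' @param movement_s,rest_s block durations in seconds.
#' @param snr_db accelerometer (and EMG rest-floor) signal-to-noise ratio in
#'   dB (default 10, a clean but non-trivial recording).
#' @param acc_tone_band_hz frequency band of the accelerometer tones.
#' @param split_information if `TRUE`, the first half of the classes differ
#'   only in their EMG patterns and the second half only in their ACC
#'   patterns, so neither modality alone can separate all classes (the
#'   designed benchmark for the fusion ablation).
#' @param seed integer seed; together with the subject id it fully
#'   determines the generated session.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(preset = c("full", "desk"), n_classes = 8,
                             n_subjects = 1, fs_hz = NULL, reps = 6,
                             movement_s = NULL, rest_s = NULL, snr_db = 10,
                             acc_tone_band_hz = c(12, 40),
                             split_information = FALSE, seed = 42) {
  preset <- match.arg(preset)
  fs_hz <- fs_hz %||% switch(preset, full = 2000, desk = 500)
  movement_s <- movement_s %||% switch(preset, full = 5, desk = 2)
  rest_s <- rest_s %||% switch(preset, full = 3, desk = 1)
  if (n_classes < 2) abort_arg("need at least 2 classes")
  if (n_classes > 49) abort_arg("at most 49 movement classes fit the label range")
  if (fs_hz <= 2 * acc_tone_band_hz[2])
    abort_arg("fs_hz must exceed twice the upper accelerometer tone frequency")
  if (reps < 1 || reps > 6) abort_arg("reps must lie in 1..6 (DB2 layout)")
  pat <- make_class_patterns(n_classes, seed = seed,
                             split_information = split_information)
  structure(list(
    preset = preset, n_classes = as.integer(n_classes),
    n_subjects = as.integer(n_subjects), fs_hz = fs_hz, reps = as.integer(reps),
    movement_s = movement_s, rest_s = rest_s, snr_db = snr_db,
    acc_tone_band_hz = acc_tone_band_hz,
    split_information = isTRUE(split_information),
    emg_pattern = pat$emg_pattern, acc_pattern = pat$acc_pattern,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Generate class-specific channel activation patterns
#'
#' Each movement class receives a row of per-channel EMG gains and a row of
#' per-channel accelerometer tone amplitudes. Every class dominates a
#' distinct subset of channels, so rows are pairwise distinct. In
#' split-information mode the first `floor(n/2)` classes share one common
#' ACC row (EMG-only separable) and the remaining classes share one common
#' EMG row (ACC-only separable).
#'
#' @param n_classes number of classes (>= 2).
#' @param seed RNG seed; identical seeds give identical matrices.
#' @param split_information see [synthetic_config()].
#' @return list with `emg_pattern` `[n_classes x 12]` and `acc_pattern`
#'   `[n_classes x 36]`.
#' @export
make_class_patterns <- function(n_classes, seed = 42, split_information = FALSE) {
  if (n_classes < 2) abort_arg("need at least 2 classes")
  n_emg <- 12L; n_acc <- 36L
  with_seed(derive_seed(seed, "patterns"), {
    emg <- matrix(runif(n_classes * n_emg, 0.05, 0.30), n_classes, n_emg)
    acc <- matrix(runif(n_classes * n_acc, 0.02, 0.10), n_classes, n_acc)
    for (k in seq_len(n_classes)) {
      # stride-5 start is coprime with 12, so dominant triples are distinct
      dom_e <- ((k - 1) * 5 + 0:2) %% n_emg + 1L
      emg[k, dom_e] <- runif(3, 1.0, 2.0)
      # dominant tone amplitudes are sized so the summed tone power clearly
      # exceeds the noise floor after band-pass filtering (>= 6 dB)
      dom_a <- ((k - 1) * 7 + 0:5) %% n_acc + 1L
      acc[k, dom_a] <- runif(6, 1.5, 2.5)
    }
    if (split_information) {
      half <- floor(n_classes / 2)
      common_acc <- runif(n_acc, 0.2, 0.4)
      common_emg <- runif(n_emg, 0.2, 0.4)
      for (k in seq_len(half)) acc[k, ] <- common_acc
      for (k in (half + 1):n_classes) emg[k, ] <- common_emg
    }
    d <- as.matrix(stats::dist(cbind(emg, acc)))
    diag(d) <- Inf
    if (min(d) <= 0) abort_arg("degenerate patterns: two classes coincide")
    list(emg_pattern = emg, acc_pattern = acc)
  })
}

# band-limited Gaussian carrier with unit variance, one column per channel
make_carrier <- function(n, n_ch, fs) {
  lo <- 20
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  z <- matrix(rnorm(n * n_ch), n, n_ch)
  for (ch in seq_len(n_ch)) {
    v <- signal::filtfilt(bf, z[, ch])
    z[, ch] <- v / sd(v)
  }
  z
}

#' Generate one synthetic recording session
#'
#' Lays out, for every class in turn, `reps` blocks of movement followed by
#' rest, annotating `stimulus` and `repetition` per sample exactly as the
#' DB2 files do. Deterministic given the config seed and the subject id.
#'
#' @param config a [synthetic_config()].
#' @param subject_id identifier; distinct subjects get distinct noise
#'   realizations but identical class patterns.
#' @return a [recording_session()].
#' @export
generate_session <- function(config, subject_id = "S1") {
  fs <- config$fs_hz
  Lm <- round(config$movement_s * fs)
  Lr <- round(config$rest_s * fs)
  K <- config$n_classes; reps <- config$reps
  n <- K * reps * (Lm + Lr)
  n_emg <- ncol(config$emg_pattern); n_acc <- ncol(config$acc_pattern)

  stimulus <- integer(n); repetition <- integer(n)
  block <- 0L
  for (k in seq_len(K)) for (r in seq_len(reps)) {
    at <- block * (Lm + Lr)
    stimulus[at + seq_len(Lm)] <- k
    repetition[at + seq_len(Lm)] <- r
    block <- block + 1L
  }

  noise_sd <- 10^(-config$snr_db / 20)
  tone_lo <- config$acc_tone_band_hz[1]; tone_hi <- config$acc_tone_band_hz[2]
  # tone frequency depends on the channel only, so classes are encoded purely
  # by their amplitude profiles (required for split-information mode)
  freqs <- tone_lo + (tone_hi - tone_lo) * (seq_len(n_acc) - 1) / (n_acc - 1)

  with_seed(derive_seed(config$seed, "session", subject_id), {
    carrier <- make_carrier(n, n_emg, fs)
    gain <- matrix(0, n, n_emg)
    amp <- matrix(0, n, n_acc)
    active <- stimulus > 0L
    gain[active, ] <- config$emg_pattern[stimulus[active], , drop = FALSE]
    amp[active, ] <- config$acc_pattern[stimulus[active], , drop = FALSE]
    emg <- carrier * gain + matrix(rnorm(n * n_emg, sd = noise_sd), n, n_emg)
    phase <- matrix(runif(K * n_acc, 0, 2 * pi), K, n_acc)
    t_sec <- (seq_len(n) - 1) / fs
    acc <- matrix(rnorm(n * n_acc, sd = noise_sd), n, n_acc)
    for (ch in seq_len(n_acc)) {
      ph <- numeric(n)
      ph[active] <- phase[stimulus[active], ch]
      acc[, ch] <- acc[, ch] + amp[, ch] * sin(2 * pi * freqs[ch] * t_sec + ph)
    }
    recording_session(emg, acc, stimulus, repetition,
                      sampling_rate_hz = fs, subject_id = subject_id)
  })
}
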