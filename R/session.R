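# Recording sessions in the NinaPro DB2 layout: 12 EMG channels at 2000 Hz,
# each electrode carrying a tri-axial accelerometer (36 ACC channels), with
# per-sample gesture label (0 = rest, 1..49 = movements) and repetition
# index (0 = rest, 1..6).

N_EMG_CHANNELS <- 12L
N_ACC_CHANNELS <- 36L
MAX_STIMULUS <- 49L
MAX_REPETITION <- 6L

#' Construct a multimodal recording session
#'
#' Bundles one subject's synchronized EMG/accelerometer streams with their
#' per-sample gesture and repetition annotations.
#'
#' @param emg numeric matrix `[n_samples x 12]`, raw sEMG (mV scale).
#' @param acc numeric matrix `[n_samples x 36]`, accelerometer channels
#'   (12 electrodes x 3 axes).
#' @param stimulus integer vector of per-sample gesture labels in `0..49`
#'   (0 = rest).
#' @param repetition integer vector of per-sample repetition indices in
#'   `0..6` (0 = rest periods).
#' @param sampling_rate_hz sampling rate in Hz (default 2000).
#' @param subject_id subject identifier.
#' @param annotation which annotation family the labels came from:
#'   `"corrected"` (movement-onset-corrected restimulus/rerepetition, the
#'   community convention for DB2 classification) or `"raw"`.
#' @return an object of class `recording_session`.
#' @export
recording_session <- function(emg, acc, stimulus, repetition,
                              sampling_rate_hz = 2000, subject_id = "S1",
                              annotation = "corrected") {
  s <- structure(list(
    emg = as.matrix(emg), acc = as.matrix(acc),
    stimulus = as.integer(round(stimulus)),
    repetition = as.integer(round(repetition)),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    subject_id = as.character(subject_id),
    annotation = annotation), class = "recording_session")
  validate_session(s)
}

#' Validate a recording session's invariants
#'
#' Checks stream lengths, channel counts, label/repetition ranges and the
#' sampling rate; returns the session invisibly augmented with `n_samples`.
#'
#' @param s a `recording_session`.
#' @return the validated session.
#' @export
validate_session <- function(s) {
  n <- nrow(s$emg)
  if (is.null(n) || n < 1L) abort_arg("session has no samples")
  if (ncol(s$emg) != N_EMG_CHANNELS)
    abort_arg("emg must have %d channels, got %d", N_EMG_CHANNELS, ncol(s$emg))
  if (ncol(s$acc) != N_ACC_CHANNELS)
    abort_arg("acc must have %d channels, got %d", N_ACC_CHANNELS, ncol(s$acc))
  lens <- c(nrow(s$acc), length(s$stimulus), length(s$repetition))
  if (any(lens != n))
    abort_arg("stream length mismatch: emg %d, acc %d, stimulus %d, repetition %d",
              n, lens[1], lens[2], lens[3])
  if (anyNA(s$stimulus) || any(s$stimulus < 0L | s$stimulus > MAX_STIMULUS))
    abort_arg("stimulus values must lie in [0, %d]", MAX_STIMULUS)
  if (anyNA(s$repetition) || any(s$repetition < 0L | s$repetition > MAX_REPETITION))
    abort_arg("repetition values must lie in [0, %d]", MAX_REPETITION)
  if (!is.finite(s$sampling_rate_hz) || s$sampling_rate_hz <= 0)
    abort_arg("sampling_rate_hz must be positive")
  s$n_samples <- n
  s
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$n_samples, x$sampling_rate_hz,
              x$n_samples / x$sampling_rate_hz))
  mv <- sort(unique(x$stimulus[x$stimulus > 0L]))
  cat(sprintf("  emg 12 ch, acc 36 ch; %d movement classes, repetitions %s; labels: %s\n",
              length(mv),
              paste(range(x$repetition[x$repetition > 0L]), collapse = "-"),
              x$annotation))
  invisible(x)
}

#' Read a recording session from a NinaPro DB2-layout MAT file
#'
#' Expects numeric fields `emg`, `acc`, a label vector and a repetition
#' vector. When both the raw (`stimulus`/`repetition`) and the
#' movement-onset-corrected (`restimulus`/`rerepetition`) annotations are
#' present, the corrected ones are used and the choice is recorded in the
#' session's `annotation` field.
#'
#' @param path path to a `.mat` file.
#' @return a validated [recording_session()].
#' @export
read_session <- function(path) {
  vars <- read_mat(path)
  for (field in c("emg", "acc"))
    if (is.null(vars[[field]]))
      abort_arg("'%s': missing required field '%s'", path, field)
  use_corrected <- !is.null(vars$restimulus) && !is.null(vars$rerepetition)
  stim <- if (use_corrected) vars$restimulus else vars$stimulus
  reps <- if (use_corrected) vars$rerepetition else vars$repetition
  if (is.null(stim))
    abort_arg("'%s': missing required field 'stimulus' (or 'restimulus')", path)
  if (is.null(reps))
    abort_arg("'%s': missing required field 'repetition' (or 'rerepetition')", path)
  fs <- if (!is.null(vars$sampling_rate_hz)) as.numeric(vars$sampling_rate_hz[1]) else 2000
  subj <- if (is.character(vars$subject_id)) vars$subject_id
          else if (!is.null(vars$subject)) paste0("S", as.integer(vars$subject[1]))
          else sub("\\.mat$", "", basename(path))
  recording_session(vars$emg, vars$acc, as.vector(stim), as.vector(reps),
                    sampling_rate_hz = fs, subject_id = subj,
                    annotation = if (use_corrected) "corrected" else "raw")
}

#' Write a session as a DB2-layout MAT fixture
#'
#' Serializes all five streams so that `read_session(write_fixture(s))`
#' reproduces them exactly. Labels are written under both the raw and the
#' corrected field names, matching the layout of the distributed files.
#'
#' @param session a valid [recording_session()].
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(session, path) {
  session <- validate_session(session)
  subj_num <- suppressWarnings(as.numeric(sub("^S", "", session$subject_id)))
  vars <- list(
    emg = session$emg,
    acc = session$acc,
    stimulus = matrix(as.double(session$stimulus), ncol = 1),
    repetition = matrix(as.double(session$repetition), ncol = 1),
    restimulus = matrix(as.double(session$stimulus), ncol = 1),
    rerepetition = matrix(as.double(session$repetition), ncol = 1),
    sampling_rate_hz = matrix(session$sampling_rate_hz),
    subject = matrix(if (is.na(subj_num)) 0 else subj_num),
    subject_id = session$subject_id)
  write_mat(vars, path)
}

#' Repetition-based train/test split
#'
#' Returns boolean masks over samples assigning each sample to the training
#' or test partition by its movement repetition index, the leakage-free
#' protocol for DB2 (repetitions 1, 3, 4, 6 train; 2, 5 test). Rest samples
#' (stimulus 0) are excluded from both masks unless `include_rest`.
#'
#' @param session a [recording_session()].
#' @param train_reps,test_reps disjoint sets of repetition indices.
#' @param include_rest keep rest samples (label 0) in the masks? Default
#'   `FALSE`, i.e. the 49-class movement task.
#' @return list with logical vectors `train` and `test`.
#' @export
split_by_repetition <- function(session, train_reps = c(1, 3, 4, 6),
                                test_reps = c(2, 5), include_rest = FALSE) {
  train_reps <- as.integer(train_reps); test_reps <- as.integer(test_reps)
  if (length(intersect(train_reps, test_reps)) > 0L)
    abort_arg("train_reps and test_reps overlap: {%s}",
              paste(intersect(train_reps, test_reps), collapse = ","))
  tr <- session$repetition %in% train_reps
  te <- session$repetition %in% test_reps
  if (!include_rest) {
    mv <- session$stimulus > 0L
    tr <- tr & mv
    te <- te & mv
  }
  list(train = tr, test = te)
}
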