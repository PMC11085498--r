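# Preprocessing chain: band-pass filtering -> z-score normalization with
# training-set statistics -> sliding-window segmentation. The order is fixed;
# each stage is exported on its own so it can be tested against independent
# oracles.

#' Band-pass filter specification
#'
#' A Butterworth band-pass, by default fourth order with a 10-500 Hz
#' passband, covering the informative sEMG band. The same filter is applied
#' to the EMG and the accelerometer streams.
#'
#' @param order overall filter order (must be even; default 4).
#' @param band_hz numeric length-2 `(low, high)` passband edges in Hz.
#' @param zero_phase apply forward-backward (zero-phase) filtering? Default
#'   `TRUE`, avoiding phase skew between the two streams; set `FALSE` for a
#'   causal (real-time style) pass.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, band_hz = c(10, 500), zero_phase = TRUE) {
  if (order < 2 || order %% 2 != 0) abort_arg("filter order must be a positive even integer")
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    abort_arg("band_hz must satisfy 0 < low < high")
  structure(list(order = as.integer(order), band_hz = as.numeric(band_hz),
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

#' Apply a Butterworth band-pass to every channel
#'
#' Channels are filtered independently. With `zero_phase = TRUE` (default)
#' the filter runs forward and backward, so the effective magnitude response
#' is the squared design response and the phase is zero.
#'
#' @param x numeric matrix `[n_samples x n_channels]`.
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), fs) {
  x <- as.matrix(x)
  nyq <- fs / 2
  if (spec$band_hz[2] >= nyq)
    abort_arg("upper band edge %g Hz must be below the Nyquist frequency %g Hz",
              spec$band_hz[2], nyq)
  if (spec$band_hz[1] >= nyq) abort_arg("lower band edge is above Nyquist")
  # signal::butter() takes the per-section order; a band-pass of section
  # order n has overall order 2n
  bf <- signal::butter(spec$order / 2, spec$band_hz / nyq, type = "pass")
  warmup <- 3 * (max(length(bf$a), length(bf$b)) - 1)
  if (nrow(x) <= warmup)
    abort_arg("signal too short for filter warm-up (%d samples needed)", warmup + 1)
  y <- x
  for (ch in seq_len(ncol(x))) {
    y[, ch] <- if (spec$zero_phase) signal::filtfilt(bf, x[, ch])
               else as.numeric(signal::filter(bf, x[, ch]))
  }
  y
}

#' Fit per-channel normalization statistics on training data
#'
#' Computes each channel's mean and standard deviation (population
#' convention, dividing by `n`) over training samples only; the same
#' statistics are later applied to the test partition so no test information
#' leaks into the normalization.
#'
#' @param x numeric matrix `[n_samples x n_channels]` of training samples.
#' @return object of class `channel_stats` with fields `mean` and `std`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort_arg("need at least 2 samples to fit channel statistics")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)
  bad <- which(!is.finite(sigma) | sigma <= 0)
  if (length(bad) > 0)
    abort_arg("channel %s has zero variance; cannot normalize",
              paste(bad, collapse = ", "))
  structure(list(mean = mu, std = sigma, convention = "population"),
            class = "channel_stats")
}

#' Apply (or invert) per-channel z-score normalization
#'
#' `apply_normalizer` computes `y = (x - mean) / std` per channel;
#' `invert_normalizer` recovers `x = y * std + mean`.
#'
#' @param x numeric matrix `[n_samples x n_channels]`.
#' @param stats a `channel_stats` object from [fit_normalizer()].
#' @return matrix of the same shape.
#' @export
apply_normalizer <- function(x, stats) {
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean))
    abort_arg("channel mismatch: data has %d channels, stats %d",
              ncol(x), length(stats$mean))
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$std, "/")
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(x, stats) {
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean))
    abort_arg("channel mismatch: data has %d channels, stats %d",
              ncol(x), length(stats$mean))
  sweep(sweep(x, 2, stats$std, "*"), 2, stats$mean, "+")
}

#' Sliding-window specification
#'
#' Converts the window length `T_ms` and step `S_ms` (milliseconds) to
#' sample counts at sampling rate `fs_hz`: `L = T * F / 1000` and
#' `Ld = S * F / 1000`. Both must come out as whole numbers of samples.
#'
#' @param T_ms window length in ms (default 200, the value selected by the
#'   window-length study).
#' @param S_ms step length in ms (default 50).
#' @param fs_hz sampling rate in Hz (default 2000).
#' @return object of class `window_spec` with fields `L` and `Ld`.
#' @export
window_spec <- function(T_ms = 200, S_ms = 50, fs_hz = 2000) {
  L <- T_ms * fs_hz / 1000
  Ld <- S_ms * fs_hz / 1000
  if (abs(L - round(L)) > 1e-9 || abs(Ld - round(Ld)) > 1e-9)
    abort_arg("window (%g ms) and step (%g ms) must be whole samples at %g Hz",
              T_ms, S_ms, fs_hz)
  L <- as.integer(round(L)); Ld <- as.integer(round(Ld))
  if (Ld < 1L || L < Ld)
    abort_arg("need L >= Ld >= 1 (got L=%d, Ld=%d)", L, Ld)
  structure(list(T_ms = T_ms, S_ms = S_ms, fs_hz = fs_hz, L = L, Ld = Ld),
            class = "window_spec")
}

#' Construct a window set
#'
#' @param x array `[n_channels x L x n_windows]` of window data.
#' @param labels integer vector of per-window gesture labels.
#' @param channel_kind `"emg"` or `"acc"`.
#' @return object of class `window_set`.
#' @export
window_set <- function(x, labels, channel_kind = c("emg", "acc")) {
  channel_kind <- match.arg(channel_kind)
  if (length(dim(x)) != 3L) abort_arg("window data must be a 3-d array")
  if (dim(x)[3] != length(labels))
    abort_arg("n_windows (%d) != n_labels (%d)", dim(x)[3], length(labels))
  structure(list(x = x, labels = as.integer(labels), channel_kind = channel_kind,
                 n_windows = dim(x)[3], n_channels = dim(x)[1], L = dim(x)[2]),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s: %d windows of %d channels x %d samples, %d classes\n",
              x$channel_kind, x$n_windows, x$n_channels, x$L,
              length(unique(x$labels))))
  invisible(x)
}

#' Segment a multichannel signal into labeled sliding windows
#'
#' Windows of `spec$L` samples start at offsets `0, Ld, 2 Ld, ...` while they
#' fit inside the signal, so a stream of `n` samples yields
#' `floor((n - L) / Ld) + 1` candidate windows. Each window is transposed to
#' `[n_channels x L]`. Labeling policy:
#' \describe{
#'   \item{`"majority"`}{(default) majority vote over the window's per-sample
#'     labels, ties broken toward the lower label; windows mixing rest (0)
#'     with movement are dropped.}
#'   \item{`"strict"`}{drop every window whose samples are not uniformly
#'     labeled.}
#' }
#'
#' @param x numeric matrix `[n_samples x n_channels]`.
#' @param labels integer per-sample labels (same length as `nrow(x)`).
#' @param spec a [window_spec()].
#' @param labeling `"majority"` or `"strict"`.
#' @return a [window_set()]; empty (with a warning) when the stream is
#'   shorter than one window.
#' @export
segment_windows <- function(x, labels, spec,
                            labeling = c("majority", "strict")) {
  labeling <- match.arg(labeling)
  x <- as.matrix(x)
  n <- nrow(x); nc <- ncol(x); L <- spec$L; Ld <- spec$Ld
  labels <- as.integer(labels)
  if (length(labels) != n) abort_arg("labels length != n_samples")
  if (n < L) {
    warning(sprintf("stream of %d samples is shorter than one window (L=%d); empty window set", n, L))
    return(window_set(array(0, dim = c(nc, L, 0)), integer(0)))
  }
  starts <- seq.int(1L, n - L + 1L, by = Ld)
  nw <- length(starts)
  # gather all windows at once: rows are (L x nw) slices of the stream
  ridx <- as.vector(outer(0:(L - 1L), starts, "+"))
  wins <- array(x[ridx, , drop = FALSE], dim = c(L, nw, nc))
  labmat <- matrix(labels[ridx], nrow = L, ncol = nw)
  first <- labmat[1L, ]
  uniform <- colSums(labmat != rep(first, each = L)) == 0L
  win_lab <- first
  keep <- rep(TRUE, nw)
  mixed <- which(!uniform)
  if (length(mixed) > 0) {
    if (labeling == "strict") {
      keep[mixed] <- FALSE
    } else {
      for (j in mixed) {
        tab <- tabulate(labmat[, j] + 1L)
        has_rest <- tab[1L] > 0L
        has_move <- any(tab[-1L] > 0L)
        if (has_rest && has_move) { keep[j] <- FALSE; next }
        win_lab[j] <- which.max(tab) - 1L  # which.max takes the lowest label on ties
      }
    }
  }
  wins <- aperm(wins[, keep, , drop = FALSE], c(3, 1, 2))
  window_set(wins, win_lab[keep])
}

#' Run the full preprocessing chain with a repetition-based split
#'
#' Filters both streams, fits normalization statistics on the training
#' samples only, applies them to both partitions, and segments each
#' contiguous run of same-partition samples into aligned EMG/ACC window
#' pairs. When the sampling rate is too low for the requested upper band
#' edge, the edge is lowered to `0.45 * fs` (with a message) so the same
#' filter specification can drive reduced-rate synthetic sessions.
#'
#' @param session a [recording_session()].
#' @param filter a [filter_spec()].
#' @param window a [window_spec()]; its `fs_hz` must match the session.
#' @param train_reps,test_reps repetition index sets for the split.
#' @param include_rest keep rest samples (50-class task)? Default `FALSE`.
#' @param labeling window labeling policy, see [segment_windows()].
#' @return list with elements `train` and `test`, each a list
#'   `(emg = window_set, acc = window_set, labels)` with aligned windows,
#'   plus the fitted `stats` per modality.
#' @export
preprocess_session <- function(session, filter = filter_spec(),
                               window = window_spec(fs_hz = session$sampling_rate_hz),
                               train_reps = c(1, 3, 4, 6), test_reps = c(2, 5),
                               include_rest = FALSE,
                               labeling = c("majority", "strict")) {
  labeling <- match.arg(labeling)
  session <- validate_session(session)
  fs <- session$sampling_rate_hz
  if (abs(window$fs_hz - fs) > 1e-9)
    abort_arg("window spec is for %g Hz but session is %g Hz", window$fs_hz, fs)
  if (filter$band_hz[2] >= fs / 2) {
    new_hi <- 0.45 * fs
    message(sprintf("upper band edge %g Hz >= Nyquist at fs %g Hz; using %g Hz",
                    filter$band_hz[2], fs, new_hi))
    filter <- filter_spec(filter$order, c(filter$band_hz[1], new_hi),
                          filter$zero_phase)
  }
  emg_f <- bandpass_filter(session$emg, filter, fs)
  acc_f <- bandpass_filter(session$acc, filter, fs)
  masks <- split_by_repetition(session, train_reps, test_reps, include_rest)

  emg_stats <- fit_normalizer(emg_f[masks$train, , drop = FALSE])
  acc_stats <- fit_normalizer(acc_f[masks$train, , drop = FALSE])
  emg_n <- apply_normalizer(emg_f, emg_stats)
  acc_n <- apply_normalizer(acc_f, acc_stats)

  segment_mask <- function(mask) {
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    emg_parts <- list(); acc_parts <- list(); lab_parts <- list()
    for (k in keep) {
      idx <- starts[k]:ends[k]
      if (length(idx) < window$L) next  # short runs tolerated silently here
      we <- segment_windows(emg_n[idx, , drop = FALSE], session$stimulus[idx],
                            window, labeling)
      wa <- segment_windows(acc_n[idx, , drop = FALSE], session$stimulus[idx],
                            window, labeling)
      stopifnot(identical(we$labels, wa$labels))
      emg_parts[[length(emg_parts) + 1L]] <- we$x
      acc_parts[[length(acc_parts) + 1L]] <- wa$x
      lab_parts[[length(lab_parts) + 1L]] <- we$labels
    }
    bind3 <- function(parts, nc, L) {
      if (length(parts) == 0) return(array(0, dim = c(nc, L, 0)))
      array(unlist(parts, use.names = FALSE),
            dim = c(nc, L, sum(vapply(parts, function(p) dim(p)[3], 0))))
    }
    labs <- unlist(lab_parts) %||% integer(0)
    list(emg = window_set(bind3(emg_parts, ncol(emg_n), window$L), labs, "emg"),
         acc = window_set(bind3(acc_parts, ncol(acc_n), window$L), labs, "acc"),
         labels = as.integer(labs))
  }
  list(train = segment_mask(masks$train),
       test = segment_mask(masks$test),
       stats = list(emg = emg_stats, acc = acc_stats),
       window = window, filter = filter)
}
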