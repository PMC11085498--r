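# Metrics and the ablation harness: per-subject window accuracy, overall
# accuracy as the unweighted mean across subjects, confusion matrices, and
# the single-stream / fused / no-attention comparison.

#' Classification accuracy
#'
#' Fraction of correctly classified gesture segments.
#'
#' @param pred,truth equal-length integer label vectors.
#' @return scalar in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    abort_arg("pred and truth must be nonempty vectors of equal length")
  mean(pred == truth)
}

#' Overall accuracy across subjects
#'
#' The unweighted mean of per-subject accuracies (not pooled over windows),
#' so every subject contributes equally regardless of window count.
#'
#' @param per_subject numeric vector of per-subject accuracies in `[0, 1]`.
#' @return scalar mean accuracy.
#' @export
overall_accuracy <- function(per_subject) {
  if (length(per_subject) == 0) abort_arg("per_subject is empty")
  if (any(per_subject < 0 | per_subject > 1))
    abort_arg("accuracies must lie in [0, 1]")
  mean(per_subject)
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts windows with true label `i` predicted as `j`;
#' labels are taken from `0..n_classes-1`.
#'
#' @param pred,truth integer label vectors in `0..n_classes-1`.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix (rows = truth).
#' @export
confusion_matrix <- function(pred, truth, n_classes) {
  if (length(pred) != length(truth)) abort_arg("pred and truth differ in length")
  if (any(pred < 0 | pred >= n_classes | truth < 0 | truth >= n_classes))
    abort_arg("labels must lie in [0, %d]", n_classes - 1)
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(truth = 0:(n_classes - 1), pred = 0:(n_classes - 1)))
  tab <- table(factor(truth, levels = 0:(n_classes - 1)),
               factor(pred, levels = 0:(n_classes - 1)))
  m[] <- as.integer(tab)
  m
}

#' Predict labels for a set of windows
#'
#' Runs the model in inference mode over the data in batches and maps the
#' argmax class index back to the training labels.
#'
#' @param model a trained model (from [train_model()] or
#'   [load_checkpoint()]).
#' @param data list with `labels` and the modalities the model needs.
#' @param batch_size inference batch size.
#' @return list with `pred`, `truth`, `accuracy` and `confusion` (indexed
#'   over the model's class set).
#' @export
evaluate_model <- function(model, data, batch_size = 256) {
  classes <- model$classes
  if (is.null(classes)) abort_arg("model has no class mapping; train it first")
  n <- length(data$labels)
  pred <- integer(n)
  for (at in seq.int(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    probs <- softmax_cols(model$fwd(.batch_inputs(data, idx), training = FALSE))
    pred[idx] <- classes[max.col(t(probs))]
  }
  truth <- data$labels
  k <- length(classes)
  cidx <- setNames(seq_along(classes) - 1L, as.character(classes))
  list(pred = pred, truth = truth,
       accuracy = accuracy(pred, truth),
       confusion = confusion_matrix(cidx[as.character(pred)],
                                    cidx[as.character(truth)], k))
}

#' Evaluation report
#'
#' @param per_subject_acc named numeric vector of per-subject accuracies.
#' @param confusion summed confusion matrix across subjects (optional).
#' @param ablation_table data frame of ablation results (optional).
#' @return object of class `eval_report` with `overall_acc` set to the
#'   unweighted mean of `per_subject_acc`.
#' @export
eval_report <- function(per_subject_acc, confusion = NULL, ablation_table = NULL) {
  oa <- overall_accuracy(per_subject_acc)
  if (!is.null(confusion)) {
    if (any(confusion < 0)) abort_arg("confusion entries must be nonnegative")
  }
  structure(list(per_subject_acc = per_subject_acc, overall_acc = oa,
                 confusion = confusion, ablation_table = ablation_table),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d subject(s), overall accuracy %.4f\n",
              length(x$per_subject_acc), x$overall_acc))
  for (nm in names(x$per_subject_acc))
    cat(sprintf("  %s: %.4f\n", nm, x$per_subject_acc[[nm]]))
  if (!is.null(x$ablation_table)) {
    cat("ablation (mean accuracy):\n")
    print(x$ablation_table)
  }
  invisible(x)
}

# condition -> model spec for a given window length and class count
.condition_spec <- function(condition, L, n_classes, preset, dropout) {
  switch(condition,
    "emg-only" = single_stream_spec(c(12, L, 1), "emg", n_classes, preset, dropout),
    "acc-only" = single_stream_spec(c(36, L, 1), "acc", n_classes, preset, dropout),
    "fused" = ,
    "fused+eca" = two_stream_spec(c(12, L, 1), c(36, L, 1), n_classes, preset, dropout,
                                  use_attention = TRUE),
    "fused-attention" = two_stream_spec(c(12, L, 1), c(36, L, 1), n_classes, preset,
                                        dropout, use_attention = FALSE),
    abort_arg("unknown condition '%s'", condition))
}

.condition_data <- function(condition, part) {
  if (condition == "emg-only") list(labels = part$labels, emg = part$emg)
  else if (condition == "acc-only") list(labels = part$labels, acc = part$acc)
  else list(labels = part$labels, emg = part$emg, acc = part$acc)
}

#' Single-stream versus fused ablation harness
#'
#' For every combination of condition, window length and seed, runs the full
#' per-subject pipeline (preprocess with the repetition split, train, test)
#' and aggregates per-subject accuracies into an overall accuracy per cell.
#' Single-stream conditions build one branch + ECA + head; `"fused"` is the
#' two-stream model with ECA and `"fused-attention"` removes the attention
#' step.
#'
#' @param sessions list of [recording_session()]s (one per subject).
#' @param conditions subset of `c("emg-only", "acc-only", "fused",
#'   "fused+eca", "fused-attention")`.
#' @param window_T_ms vector of window lengths in ms (default 200).
#' @param config a [train_config()].
#' @param seeds integer vector of replicate seeds (default 1).
#' @param preset model preset (default `"small"`).
#' @param filter a [filter_spec()].
#' @param S_ms window step in ms (default 50).
#' @param train_reps,test_reps repetition split.
#' @return an [eval_report()] whose `ablation_table` has one row per
#'   (condition, T_ms, seed) with the mean accuracy across subjects, and a
#'   `per_subject` attribute with the full grid.
#' @export
run_ablation <- function(sessions, conditions = c("emg-only", "acc-only", "fused"),
                         window_T_ms = 200, config = train_config(),
                         seeds = 1, preset = "small", filter = filter_spec(),
                         S_ms = 50, train_reps = c(1, 3, 4, 6), test_reps = c(2, 5)) {
  if (length(sessions) < 1) abort_arg("need at least one session")
  if (inherits(sessions, "recording_session")) sessions <- list(sessions)
  known <- c("emg-only", "acc-only", "fused", "fused+eca", "fused-attention")
  bad <- setdiff(conditions, known)
  if (length(bad) > 0) abort_arg("unknown condition(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (T_ms in window_T_ms) {
    # preprocess each subject once per window length; all conditions share it
    prepped <- lapply(sessions, function(s) {
      preprocess_session(s, filter,
                         window_spec(T_ms, S_ms, s$sampling_rate_hz),
                         train_reps, test_reps)
    })
    for (condition in conditions) {
      for (seed in seeds) {
        for (si in seq_along(sessions)) {
          pp <- prepped[[si]]
          n_classes <- length(unique(pp$train$labels))
          L <- pp$window$L
          spec <- .condition_spec(condition, L, n_classes, preset, config$dropout)
          cfg <- config
          cfg$seed <- derive_seed(seed, condition, si)
          fit <- train_model(spec, .condition_data(condition, pp$train), cfg)
          ev <- evaluate_model(fit$model, .condition_data(condition, pp$test),
                               config$batch_size)
          rows[[length(rows) + 1L]] <- data.frame(
            condition = condition, T_ms = T_ms, seed = seed,
            subject = sessions[[si]]$subject_id, accuracy = ev$accuracy)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ condition + T_ms + seed, data = grid,
                          FUN = overall_accuracy)
  names(agg)[names(agg) == "accuracy"] <- "mean_accuracy"
  per_subject <- vapply(split(grid$accuracy, grid$subject), mean, 0)
  rep <- eval_report(per_subject, ablation_table = agg)
  attr(rep, "per_subject_grid") <- grid
  rep
}
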