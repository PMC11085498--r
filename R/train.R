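# Training: one-hot cross-entropy, stratified validation split, AdamW-style
# optimizer (decoupled weight decay), and the reduce-on-plateau learning-rate
# schedule (factor 0.1, patience 1) with best-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the study protocol: 30 epochs, batch size 256, Adam with
#' initial learning rate 0.001 and weight-decay factor 0.0005, learning rate
#' multiplied by 0.1 after every plateau of the validation loss (patience 1
#' epoch), dropout 0.5 between the fully connected layers, and one tenth of
#' the training windows held out for validation.
#'
#' @param epochs number of epochs (default 30).
#' @param batch_size minibatch size (default 256).
#' @param initial_lr initial learning rate (default 0.001).
#' @param weight_decay decoupled weight-decay factor (default 0.0005),
#'   applied to convolution and dense weights only.
#' @param lr_factor plateau multiplier (default 0.1).
#' @param lr_patience epochs without improvement before a drop (default 1).
#' @param min_lr learning-rate floor (default 1e-6).
#' @param dropout dropout rate of the fusion head (default 0.5).
#' @param val_fraction fraction of training windows held out for validation
#'   (default 0.1).
#' @param monitor plateau monitor, `"val_loss"` (default) or `"val_acc"`.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @param verbose print per-epoch progress?
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 256, initial_lr = 0.001,
                         weight_decay = 0.0005, lr_factor = 0.1,
                         lr_patience = 1, min_lr = 1e-6, dropout = 0.5,
                         val_fraction = 0.1, monitor = c("val_loss", "val_acc"),
                         seed = 1, verbose = FALSE) {
  monitor <- match.arg(monitor)
  if (epochs < 1) abort_arg("epochs must be >= 1")
  if (lr_factor <= 0 || lr_factor >= 1) abort_arg("lr_factor must lie in (0, 1)")
  if (val_fraction < 0 || val_fraction >= 1) abort_arg("val_fraction must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, dropout = dropout, val_fraction = val_fraction,
                 monitor = monitor, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "train_config")
}

#' One-hot cross-entropy loss
#'
#' Mean over samples of `-sum_i y_i log(yhat_i)`, with predicted
#' probabilities floored at `eps` inside the logarithm so saturated
#' predictions cannot produce non-finite loss.
#'
#' @param y_true one-hot matrix `[n x n_classes]`.
#' @param y_pred probability matrix `[n x n_classes]`; rows must sum to 1
#'   within `1e-6`.
#' @param eps numerical floor inside the log (default 1e-12).
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(y_true, y_pred, eps = 1e-12) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    abort_arg("y_true (%dx%d) and y_pred (%dx%d) differ in shape",
              nrow(y_true), ncol(y_true), nrow(y_pred), ncol(y_pred))
  if (any(abs(rowSums(y_pred) - 1) > 1e-6))
    abort_arg("rows of y_pred must sum to 1")
  -mean(rowSums(y_true * log(pmax(y_pred, eps))))
}

#' Stratified validation split of paired window sets
#'
#' Splits windows into training and validation parts, stratified by label
#' so each class contributes proportionally, deterministic given `seed`.
#' The EMG/ACC pairing is preserved (both modalities are indexed by the same
#' permutation). Classes with fewer than two windows trigger a fallback to
#' an unstratified split with a warning.
#'
#' @param data list with `labels` and one or both of `emg`/`acc`
#'   [window_set()]s (as produced by [preprocess_session()]).
#' @param val_fraction fraction in `[0, 1)` for validation.
#' @param seed integer seed.
#' @return list with elements `train` and `val`, each shaped like `data`.
#' @export
split_validation <- function(data, val_fraction = 0.1, seed = 1) {
  if (val_fraction < 0 || val_fraction >= 1)
    abort_arg("val_fraction must lie in [0, 1)")
  labels <- data$labels
  n <- length(labels)
  val_idx <- integer(0)
  if (val_fraction > 0) {
    counts <- table(labels)
    if (any(counts < 2)) {
      warning("some classes have fewer than 2 windows; falling back to an unstratified split")
      val_idx <- with_seed(derive_seed(seed, "valsplit"),
                           sample.int(n, size = round(val_fraction * n)))
    } else {
      val_idx <- with_seed(derive_seed(seed, "valsplit"), {
        unlist(lapply(split(seq_len(n), labels), function(idx) {
          k <- round(val_fraction * length(idx))
          if (k > 0) sample(idx, k) else integer(0)
        }), use.names = FALSE)
      })
    }
  }
  take <- function(idx) {
    out <- list(labels = labels[idx])
    for (nm in intersect(c("emg", "acc"), names(data))) {
      ws <- data[[nm]]
      out[[nm]] <- window_set(ws$x[, , idx, drop = FALSE], ws$labels[idx],
                              ws$channel_kind)
    }
    out
  }
  list(train = take(setdiff(seq_len(n), val_idx)), val = take(sort(val_idx)))
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Functional scheduler mirroring the training protocol: whenever the
#' monitored value fails to improve for `patience` consecutive epochs, the
#' learning rate is multiplied by `factor` (floored at `min_lr`). The state
#' records the number of triggered drops, so the active rate is always
#' `initial_lr * factor^drops`.
#'
#' @param initial_lr starting learning rate.
#' @param factor multiplier in (0, 1), default 0.1.
#' @param patience epochs without improvement tolerated before a drop
#'   (default 1).
#' @param min_lr floor (default 1e-6).
#' @param mode `"min"` (monitor should decrease, e.g. loss) or `"max"`.
#' @return scheduler state list; advance it with [scheduler_step()].
#' @export
plateau_scheduler <- function(initial_lr = 0.001, factor = 0.1, patience = 1,
                              min_lr = 1e-6, mode = c("min", "max")) {
  mode <- match.arg(mode)
  list(lr = initial_lr, initial_lr = initial_lr, factor = factor,
       patience = as.integer(patience), min_lr = min_lr, mode = mode,
       best = if (mode == "min") Inf else -Inf, wait = 0L, drops = 0L)
}

#' @rdname plateau_scheduler
#' @param state a scheduler state.
#' @param value the epoch's monitored value.
#' @export
scheduler_step <- function(state, value) {
  improved <- if (state$mode == "min") value < state$best else value > state$best
  if (improved) {
    state$best <- value
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr)
      state$drops <- state$drops + 1L
      state$wait <- 0L
    }
  }
  state
}

# AdamW step over all parameter-holding layers; `opt` is a mutable state env
adamw_init <- function(layers) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- vector("list", length(layers))
  opt$v <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    opt$m[[i]] <- lapply(layers[[i]]$params, function(p) p * 0)  # shape-preserving zeros
    opt$v[[i]] <- opt$m[[i]]
  }
  opt
}

adamw_step <- function(layers, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      m <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g
      v <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g^2
      opt$m[[i]][[nm]] <- m
      opt$v[[i]][[nm]] <- v
      upd <- (m / bc1) / (sqrt(v / bc2) + eps)
      if (nm %in% ly$decay) upd <- upd + weight_decay * ly$params[[nm]]
      ly$params[[nm]] <- ly$params[[nm]] - lr * upd
    }
  }
  invisible(NULL)
}

# assemble the network inputs for a subset of window indices
.batch_inputs <- function(data, idx) {
  out <- list()
  for (nm in intersect(c("emg", "acc"), names(data))) {
    x <- data[[nm]]$x[, , idx, drop = FALSE]
    dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
    out[[nm]] <- x
  }
  out
}

.eval_epoch <- function(model, data, class_map, batch_size) {
  n <- length(data$labels)
  y_idx <- class_map[as.character(data$labels)]
  loss <- 0; correct <- 0L
  for (at in seq.int(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    logits <- model$fwd(.batch_inputs(data, idx), training = FALSE)
    probs <- softmax_cols(logits)
    yi <- y_idx[idx]
    picked <- probs[cbind(yi, seq_along(idx))]
    loss <- loss + sum(-log(pmax(picked, 1e-12)))
    correct <- correct + sum(max.col(t(probs)) == yi)
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a model on paired window sets
#'
#' Minimizes one-hot cross-entropy with an adaptive-moment optimizer using
#' decoupled weight decay, under the reduce-on-plateau schedule. A
#' stratified `val_fraction` of the windows is held out; after every epoch
#' the validation loss drives the schedule and the best validation accuracy
#' determines the returned checkpoint. Fully deterministic given
#' `config$seed`.
#'
#' @param model a built model (see [build_two_stream()]), or a
#'   `two_stream_spec` which will be built with `config$seed`.
#' @param data list with `labels` and the window sets the model's branches
#'   need (`emg` and/or `acc`), e.g. the `train` element of
#'   [preprocess_session()].
#' @param config a [train_config()].
#' @return list with `model` (best checkpoint restored), `history`
#'   (per-epoch data frame), and `classes` (label mapping).
#' @export
train_model <- function(model, data, config = train_config()) {
  if (inherits(model, "two_stream_spec")) model <- build_two_stream(model, config$seed)
  n_all <- length(data$labels)
  if (n_all < 2) abort_arg("training data is empty")
  classes <- sort(unique(data$labels))
  if (length(classes) < 2) abort_arg("need at least 2 classes to train")
  if (length(classes) > model$spec$n_classes)
    abort_arg("data has %d classes but the model head has %d",
              length(classes), model$spec$n_classes)
  class_map <- setNames(seq_along(classes), as.character(classes))
  model$classes <- classes

  parts <- split_validation(data, config$val_fraction, config$seed)
  tr <- parts$train; va <- parts$val
  has_val <- length(va$labels) > 0
  layers <- collect_layers(model)
  opt <- adamw_init(layers)
  sched <- plateau_scheduler(config$initial_lr, config$lr_factor,
                             config$lr_patience, config$min_lr, mode = "min")
  n_tr <- length(tr$labels)
  y_idx <- class_map[as.character(tr$labels)]
  K <- model$spec$n_classes
  history <- vector("list", config$epochs)
  best_acc <- -Inf; best_params <- NULL

  with_seed(derive_seed(config$seed, "trainloop"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- sched$lr
      perm <- sample.int(n_tr)
      ep_loss <- 0; ep_correct <- 0L
      for (at in seq.int(1L, n_tr, by = config$batch_size)) {
        idx <- perm[at:min(at + config$batch_size - 1L, n_tr)]
        nb <- length(idx)
        logits <- model$fwd(.batch_inputs(tr, idx), training = TRUE)
        probs <- softmax_cols(logits)
        yi <- y_idx[idx]
        Y <- matrix(0, K, nb); Y[cbind(yi, seq_len(nb))] <- 1
        picked <- probs[cbind(yi, seq_len(nb))]
        batch_loss <- mean(-log(pmax(picked, 1e-12)))
        if (!is.finite(batch_loss))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
               call. = FALSE)
        ep_loss <- ep_loss + batch_loss * nb
        ep_correct <- ep_correct + sum(max.col(t(probs)) == yi)
        model$bwd((probs - Y) / nb)
        adamw_step(layers, opt, lr, config$weight_decay)
      }
      val <- if (has_val) .eval_epoch(model, va, class_map, config$batch_size)
             else list(loss = ep_loss / n_tr, acc = ep_correct / n_tr)
      monitor_value <- if (config$monitor == "val_loss") val$loss else -val$acc
      sched <- scheduler_step(sched, monitor_value)
      if (val$acc > best_acc) {
        best_acc <- val$acc
        best_params <- get_params(model)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / n_tr, train_acc = ep_correct / n_tr,
        val_loss = val$loss, val_acc = val$acc)
      if (config$verbose)
        message(sprintf("epoch %2d  lr %.2g  train %.4f/%.3f  val %.4f/%.3f",
                        epoch, lr, ep_loss / n_tr, ep_correct / n_tr,
                        val$loss, val$acc))
    }
  })
  if (!is.null(best_params)) set_params(model, best_params)
  list(model = model, history = do.call(rbind, history), classes = classes)
}
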