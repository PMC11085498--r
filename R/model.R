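# Branch and two-stream model builders. A branch is stem -> residual stages
# -> global average pooling (-> ECA); the two-stream model runs one branch
# per modality, applies efficient channel attention to each pooled vector,
# concatenates, and classifies through a dropout-regularized dense head.

#' Branch specification
#'
#' The `"full"` preset follows the ResNet-18 layout: four stages of widths
#' 64/128/256/512 with two residual blocks each, stem of a 7x7 convolution
#' plus 3x3 max-pooling. The `"small"` preset is a desk-scale variant with
#' two stages of widths 16/32 (one block each) emitting a 32-vector. For
#' image-shaped inputs (first axis >= 64 rows) the stem strides both axes as
#' in the original layout; for signal-shaped inputs (12 or 36 electrode
#' rows x time samples) the stem strides and pools along the time axis only
#' (both axes once the electrode axis is wide enough), so the electrode
#' dimension is not collapsed prematurely.
#'
#' @param input_shape integer `(rows, cols, planes)`; e.g. `c(12, 400, 1)`
#'   for EMG windows of 400 samples, `c(36, 400, 1)` for ACC.
#' @param preset `"full"` or `"small"`.
#' @return object of class `branch_spec` with the resolved stage widths,
#'   block counts and stem geometry.
#' @export
branch_spec <- function(input_shape, preset = c("full", "small")) {
  preset <- match.arg(preset)
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  if (length(input_shape) != 3L) abort_arg("input_shape must be (rows, cols, planes)")
  H <- input_shape[1]
  image_mode <- H >= 64
  if (preset == "full") {
    widths <- c(64L, 128L, 256L, 512L); blocks <- c(2L, 2L, 2L, 2L)
    stem_k <- if (image_mode) c(7L, 7L) else c(3L, 7L)
  } else {
    widths <- c(16L, 32L); blocks <- c(1L, 1L)
    stem_k <- c(3L, 3L)
  }
  stem_stride <- if (image_mode) c(2L, 2L) else if (H >= 24) c(2L, 2L) else c(1L, 2L)
  pool_geom <- if (image_mode) list(k = c(3L, 3L), s = c(2L, 2L), p = c(1L, 1L))
               else list(k = c(1L, 3L), s = c(1L, 2L), p = c(0L, 1L))
  structure(list(input_shape = as.integer(input_shape), preset = preset,
                 widths = widths, blocks = blocks, image_mode = image_mode,
                 stem_k = stem_k, stem_stride = stem_stride, pool = pool_geom,
                 out_dim = widths[length(widths)]),
            class = "branch_spec")
}

#' Build a branch network
#'
#' Instantiates the stem, residual stages and global average pooling of a
#' [branch_spec()], with He-initialized weights drawn deterministically from
#' `seed`.
#'
#' @param spec a [branch_spec()].
#' @param seed integer seed for weight initialization.
#' @return a branch object (environment) with `fwd`/`bwd` closures; its
#'   forward output is a `(out_dim x N)` matrix of pooled feature vectors.
#' @export
build_branch <- function(spec, seed = 1) {
  with_seed(derive_seed(seed, "branch", spec$preset, spec$input_shape[1]), {
    .build_branch_impl(spec)
  })
}

.build_branch_impl <- function(spec) {
  self <- new_layer("branch")
  self$spec <- spec
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  if (H < 1 || W < spec$stem_k[2])
    abort_arg(paste0("input (%d x %d) is thinner than the stem's receptive field; ",
                     "use longer windows or the 'small' preset"), H, W)
  self$stem <- list(
    conv = nn_conv2d(spec$input_shape[3], spec$widths[1],
                     spec$stem_k[1], spec$stem_k[2],
                     stride = spec$stem_stride,
                     pad = c((spec$stem_k[1] - 1L) %/% 2L, (spec$stem_k[2] - 1L) %/% 2L)),
    bn = nn_batchnorm(spec$widths[1]),
    relu = nn_relu(),
    pool = nn_maxpool(spec$pool$k[1], spec$pool$k[2], spec$pool$s, spec$pool$p))
  # track spatial size through the stem to pick per-stage strides
  cur_h <- (H + 2 * ((spec$stem_k[1] - 1L) %/% 2L) - spec$stem_k[1]) %/% spec$stem_stride[1] + 1L
  cur_h <- (cur_h + 2 * spec$pool$p[1] - spec$pool$k[1]) %/% spec$pool$s[1] + 1L
  self$stages <- list()
  c_in <- spec$widths[1]
  for (st in seq_along(spec$widths)) {
    stage <- list()
    for (b in seq_len(spec$blocks[st])) {
      first <- (b == 1L)
      downsample <- first && st > 1L
      stride <- if (!downsample) c(1L, 1L)
                else c(if (spec$image_mode || cur_h >= 4L) 2L else 1L, 2L)
      stage[[b]] <- nn_resblock(c_in, spec$widths[st], stride)
      if (downsample) cur_h <- (cur_h + 2L - 3L) %/% stride[1] + 1L
      c_in <- spec$widths[st]
    }
    self$stages[[st]] <- stage
  }
  self$gap <- nn_gap()
  self$out_dim <- spec$out_dim
  self$fwd <- function(x, training = FALSE) {
    x <- self$stem$pool$fwd(self$stem$relu$fwd(
      self$stem$bn$fwd(self$stem$conv$fwd(x, training), training), training))
    for (st in seq_along(self$stages))
      for (blk in self$stages[[st]]) x <- blk$fwd(x, training)
    self$gap$fwd(x, training)
  }
  self$bwd <- function(dy) {
    dx <- self$gap$bwd(dy)
    for (st in rev(seq_along(self$stages)))
      for (blk in rev(self$stages[[st]])) dx <- blk$bwd(dx)
    self$stem$conv$bwd(self$stem$bn$bwd(self$stem$relu$bwd(self$stem$pool$bwd(dx))))
  }
  self$children <- function() {
    c(list(self$stem$conv, self$stem$bn), unlist(self$stages, recursive = FALSE))
  }
  self
}

#' Spatial sizes after each residual stage
#'
#' Runs a probe input through the branch and reports the `(rows, cols)`
#' output size of every stage — for the full preset on a 224 x 224 probe
#' these are the classical 56/28/14/7 of the ResNet-18 layout.
#'
#' @param branch a built branch.
#' @param input_shape probe shape `(rows, cols, planes)`; defaults to the
#'   branch's own input shape.
#' @return integer matrix with one row per stage.
#' @export
branch_stage_sizes <- function(branch, input_shape = branch$spec$input_shape) {
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  probe_spec <- branch_spec(input_shape, branch$spec$preset)
  probe <- with_seed(1, .build_branch_impl(probe_spec))
  x <- array(0, dim = c(input_shape, 1L))
  trace <- list()
  # re-run forward capturing per-stage dims
  x <- probe$stem$pool$fwd(probe$stem$relu$fwd(
    probe$stem$bn$fwd(probe$stem$conv$fwd(x, FALSE), FALSE), FALSE))
  for (st in seq_along(probe$stages)) {
    for (blk in probe$stages[[st]]) x <- blk$fwd(x, FALSE)
    trace[[st]] <- dim(x)[1:2]
  }
  m <- do.call(rbind, trace)
  dimnames(m) <- list(paste0("stage", seq_len(nrow(m))), c("rows", "cols"))
  m
}

#' Two-stream model specification
#'
#' @param emg_input,acc_input input shapes of the two branches, e.g.
#'   `c(12, 400, 1)` and `c(36, 400, 1)`.
#' @param n_classes number of gesture classes (>= 2).
#' @param preset branch preset, `"full"` or `"small"`.
#' @param dropout_rate dropout between the fully connected layers
#'   (default 0.5).
#' @param use_attention apply efficient channel attention to each branch's
#'   pooled vector? Default `TRUE`; `FALSE` gives the no-attention ablation.
#' @param gamma,lam ECA kernel-size hyperparameters.
#' @param hidden width of the fusion head's hidden layer (`NULL` = 128 for
#'   the full preset, 64 for small).
#' @return object of class `two_stream_spec`.
#' @export
two_stream_spec <- function(emg_input = c(12, 400, 1), acc_input = c(36, 400, 1),
                            n_classes, preset = c("full", "small"),
                            dropout_rate = 0.5, use_attention = TRUE,
                            gamma = 2, lam = 1, hidden = NULL) {
  preset <- match.arg(preset)
  if (n_classes < 2) abort_arg("n_classes must be at least 2")
  if (dropout_rate < 0 || dropout_rate >= 1) abort_arg("dropout_rate must lie in [0, 1)")
  branches <- list()
  if (!is.null(emg_input)) branches$emg <- branch_spec(emg_input, preset)
  if (!is.null(acc_input)) branches$acc <- branch_spec(acc_input, preset)
  if (length(branches) == 0) abort_arg("at least one branch input is required")
  fused <- sum(vapply(branches, function(b) b$out_dim, 0L))
  structure(list(branches = branches, n_classes = as.integer(n_classes),
                 preset = preset, dropout_rate = dropout_rate,
                 use_attention = isTRUE(use_attention), gamma = gamma, lam = lam,
                 fused_dim = fused,
                 hidden = as.integer(hidden %||% if (preset == "full") 128L else 64L)),
            class = "two_stream_spec")
}

#' Single-stream specification (one modality only)
#'
#' Convenience wrapper building a [two_stream_spec()] with a single branch
#' plus ECA and the same head, used by the ablation harness.
#'
#' @param input branch input shape.
#' @param modality `"emg"` or `"acc"`.
#' @inheritParams two_stream_spec
#' @return a `two_stream_spec` with one branch.
#' @export
single_stream_spec <- function(input, modality = c("emg", "acc"), n_classes,
                               preset = c("full", "small"), dropout_rate = 0.5,
                               use_attention = TRUE) {
  modality <- match.arg(modality)
  if (modality == "emg")
    two_stream_spec(emg_input = input, acc_input = NULL, n_classes = n_classes,
                    preset = preset, dropout_rate = dropout_rate,
                    use_attention = use_attention)
  else
    two_stream_spec(emg_input = NULL, acc_input = input, n_classes = n_classes,
                    preset = preset, dropout_rate = dropout_rate,
                    use_attention = use_attention)
}

#' Build the (one- or two-stream) classification model
#'
#' Per modality: branch -> global average pooling -> ECA (unless disabled).
#' The attended vectors are concatenated, passed through one hidden dense
#' layer with ReLU, dropout, and a final dense + softmax head.
#'
#' @param spec a [two_stream_spec()] (or [single_stream_spec()]).
#' @param seed integer seed for weight initialization.
#' @return a model object (environment).
#' @export
build_two_stream <- function(spec, seed = 1) {
  self <- new_layer("two_stream")
  self$spec <- spec
  self$branches <- list()
  self$eca <- list()
  for (nm in names(spec$branches)) {
    self$branches[[nm]] <- build_branch(spec$branches[[nm]], seed = derive_seed(seed, nm))
    if (spec$use_attention) {
      self$eca[[nm]] <- with_seed(derive_seed(seed, nm, "eca"),
        nn_eca(spec$branches[[nm]]$out_dim, spec$gamma, spec$lam))
    }
  }
  with_seed(derive_seed(seed, "head"), {
    self$fc1 <- nn_dense(spec$fused_dim, spec$hidden)
    self$relu <- nn_relu()
    self$drop <- nn_dropout(spec$dropout_rate)
    self$fc2 <- nn_dense(spec$hidden, spec$n_classes)
  })
  self$fwd <- function(inputs, training = FALSE) {
    feats <- list()
    for (nm in names(self$branches)) {
      v <- self$branches[[nm]]$fwd(inputs[[nm]], training)
      if (!is.null(self$eca[[nm]])) v <- self$eca[[nm]]$fwd(v, training)
      feats[[nm]] <- v
    }
    fused <- do.call(rbind, feats)
    self$split_sizes <- vapply(feats, nrow, 0L)
    self$fc2$fwd(self$drop$fwd(self$relu$fwd(self$fc1$fwd(fused, training),
                                             training), training), training)
  }
  self$bwd <- function(dlogits) {
    dfused <- self$fc1$bwd(self$relu$bwd(self$drop$bwd(self$fc2$bwd(dlogits))))
    off <- 0L
    for (nm in names(self$branches)) {
      sz <- self$split_sizes[[nm]]
      dv <- dfused[(off + 1L):(off + sz), , drop = FALSE]
      if (!is.null(self$eca[[nm]])) dv <- self$eca[[nm]]$bwd(dv)
      self$branches[[nm]]$bwd(dv)
      off <- off + sz
    }
    invisible(NULL)
  }
  self$children <- function() {
    c(unname(self$branches), unname(self$eca), list(self$fc1, self$fc2))
  }
  self
}

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max), "-"))
  sweep(z, 2, colSums(z), "/")
}

#' Forward pass: class probabilities for aligned window pairs
#'
#' @param model a built model.
#' @param emg numeric array `[12 x L x n]` of EMG windows (or `NULL` for an
#'   ACC-only model).
#' @param acc numeric array `[36 x L x n]` of ACC windows (or `NULL`).
#' @param training run in training mode (batch statistics, dropout)?
#' @return `n_classes x n` matrix of probabilities; columns sum to 1.
#' @export
model_forward <- function(model, emg = NULL, acc = NULL, training = FALSE) {
  inputs <- list()
  counts <- integer(0)
  if ("emg" %in% names(model$branches)) {
    if (is.null(emg)) abort_arg("model has an EMG branch but no EMG windows given")
    if (length(dim(emg)) == 3L) dim(emg) <- c(dim(emg)[1], dim(emg)[2], 1L, dim(emg)[3])
    inputs$emg <- emg; counts <- c(counts, dim(emg)[4])
  }
  if ("acc" %in% names(model$branches)) {
    if (is.null(acc)) abort_arg("model has an ACC branch but no ACC windows given")
    if (length(dim(acc)) == 3L) dim(acc) <- c(dim(acc)[1], dim(acc)[2], 1L, dim(acc)[3])
    inputs$acc <- acc; counts <- c(counts, dim(acc)[4])
  }
  if (length(unique(counts)) > 1)
    abort_arg("EMG and ACC batches have different sizes (%s)",
              paste(counts, collapse = " vs "))
  softmax_cols(model$fwd(inputs, training = training))
}

# ---- parameter (de)serialization ------------------------------------------

#' Extract / restore all model parameters
#'
#' `get_params` returns a plain list (weights plus batch-norm running
#' statistics) suitable for checkpointing; `set_params` writes such a list
#' back into a structurally identical model.
#'
#' @param model a built model.
#' @param params a list previously returned by `get_params`.
#' @return `get_params`: a list; `set_params`: the model, invisibly.
#' @export
get_params <- function(model) {
  layers <- collect_layers(model)
  lapply(layers, function(ly) {
    p <- ly$params
    if (ly$type == "batchnorm")
      p <- c(p, list(.running_mean = ly$running_mean, .running_var = ly$running_var))
    p
  })
}

#' @rdname get_params
#' @export
set_params <- function(model, params) {
  layers <- collect_layers(model)
  if (length(layers) != length(params))
    abort_arg("checkpoint has %d parameter groups but model has %d",
              length(params), length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; p <- params[[i]]
    if (ly$type == "batchnorm") {
      ly$running_mean <- p$.running_mean
      ly$running_var <- p$.running_var
      p$.running_mean <- NULL; p$.running_var <- NULL
    }
    ly$params <- p
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the model spec, its parameters and the class-label
#' mapping, so `load_checkpoint` rebuilds an identical inference model.
#'
#' @param model a trained model (with a `classes` attribute when trained via
#'   [train_model()]).
#' @param path file path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: a model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = get_params(model),
               classes = model$classes), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_two_stream(ck$spec, seed = 1)
  set_params(model, ck$params)
  model$classes <- ck$classes
  model
}
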