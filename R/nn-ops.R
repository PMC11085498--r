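# Functional forms of the attention and residual-block operations, exposed
# so each can be checked against explicit loop oracles independently of the
# trainable layer machinery (which shares the same primitives).

#' Adaptive ECA kernel size
#'
#' Efficient channel attention chooses its 1-D convolution length from the
#' channel count: `k` is the odd integer nearest to
#' `log2(C) / gamma + lam / gamma`, ties between equidistant odd integers
#' broken downward, clamped to at least 1. With the default `gamma = 2`,
#' `lam = 1`: C = 512 gives k = 5, C = 64 gives k = 3.
#'
#' @param C number of feature channels (>= 1).
#' @param gamma,lam integers controlling how fast `k` grows with `C`
#'   (defaults 2 and 1).
#' @return an odd integer kernel size.
#' @export
eca_kernel_size <- function(C, gamma = 2, lam = 1) {
  if (length(C) != 1 || !is.finite(C) || C < 1)
    abort_arg("C must be a positive integer")
  t <- log2(C) / gamma + lam / gamma
  lower <- 2 * floor((t - 1) / 2) + 1          # greatest odd <= t (or nearest below)
  k <- if (t - lower > (lower + 2) - t) lower + 2 else lower
  max(1L, as.integer(k))
}

#' Channel-wise global average pooling
#'
#' Averages each feature channel over its full spatial extent:
#' `g(x)_c = (1 / (W H)) * sum_ij x_ijc`.
#'
#' @param fm numeric array `[W x H x C]` (a single feature map) or
#'   `[W x H x C x N]` (a batch).
#' @return numeric vector of length `C`, or a `C x N` matrix for a batch.
#' @export
global_average_pool <- function(fm) {
  d <- dim(fm)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    abort_arg("feature map must be a 3-d or 4-d array")
  if (d[1] * d[2] < 1) abort_arg("feature map has empty spatial extent")
  if (length(d) == 3L) {
    colSums(matrix(fm, nrow = d[1] * d[2])) / (d[1] * d[2])
  } else {
    matrix(colSums(matrix(fm, nrow = d[1] * d[2])) / (d[1] * d[2]), d[3], d[4])
  }
}

#' ECA specification
#'
#' @param C channel count the attention operates on.
#' @param gamma,lam kernel-size hyperparameters, see [eca_kernel_size()].
#' @param conv_weights optional numeric kernel of length
#'   `eca_kernel_size(C, gamma, lam)`; zeros by default.
#' @return object of class `eca_spec`.
#' @export
eca_spec <- function(C, gamma = 2, lam = 1, conv_weights = NULL) {
  k <- eca_kernel_size(C, gamma, lam)
  conv_weights <- conv_weights %||% numeric(k)
  if (length(conv_weights) != k)
    abort_arg("conv_weights must have length k = %d for C = %d", k, C)
  structure(list(C = as.integer(C), gamma = gamma, lam = lam, k = k,
                 conv_weights = as.numeric(conv_weights)), class = "eca_spec")
}

#' Efficient channel attention over a pooled channel vector
#'
#' Convolves the globally pooled channel descriptor with a single shared
#' 1-D kernel of length `k` (stride 1, symmetric zero padding `(k-1)/2`),
#' squashes through a sigmoid to per-channel weights in (0, 1), and rescales
#' the descriptor elementwise: `attended_c = omega_c * pooled_c`.
#'
#' @param pooled numeric vector of length `C` (or `C x N` matrix).
#' @param spec an [eca_spec()].
#' @return list with `weights` and `attended`, shaped like `pooled`.
#' @export
eca_attend <- function(pooled, spec) {
  vec_in <- is.null(dim(pooled))
  p <- if (vec_in) matrix(pooled, ncol = 1) else pooled
  if (nrow(p) != spec$C)
    abort_arg("pooled has %d channels but spec expects %d", nrow(p), spec$C)
  cv <- .eca_conv(p, spec$conv_weights)
  omega <- 1 / (1 + exp(-cv$s))
  attended <- omega * p
  if (vec_in) list(weights = as.vector(omega), attended = as.vector(attended))
  else list(weights = omega, attended = attended)
}

#' Residual block specification
#'
#' Two 3x3 convolution stages, each followed by batch normalization, with a
#' rectified-linear activation between them and after the additive shortcut.
#' The shortcut is the identity when the shape is preserved and a strided
#' 1x1 projection convolution (plus batch normalization) otherwise.
#'
#' @param in_channels,out_channels feature-channel counts.
#' @param stride spatial stride (1 or 2) of the first convolution, applied
#'   along both axes.
#' @return object of class `residual_block_spec`.
#' @export
residual_block_spec <- function(in_channels, out_channels, stride = 1) {
  if (!stride %in% c(1, 2)) abort_arg("stride must be 1 or 2")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride),
                 projection = (stride != 1 || in_channels != out_channels)),
            class = "residual_block_spec")
}

# default (inference-neutral) parameter set for a residual block: zero conv
# kernels, unit-gamma/zero-beta batch norm with standard-normal running stats
residual_block_params <- function(spec) {
  list(
    conv1 = array(0, c(3, 3, spec$in_channels, spec$out_channels)),
    bn1 = list(gamma = rep(1, spec$out_channels), beta = rep(0, spec$out_channels),
               mean = rep(0, spec$out_channels), var = rep(1, spec$out_channels)),
    conv2 = array(0, c(3, 3, spec$out_channels, spec$out_channels)),
    bn2 = list(gamma = rep(1, spec$out_channels), beta = rep(0, spec$out_channels),
               mean = rep(0, spec$out_channels), var = rep(1, spec$out_channels)),
    proj = if (spec$projection)
      array(0, c(1, 1, spec$in_channels, spec$out_channels)),
    proj_bn = if (spec$projection)
      list(gamma = rep(1, spec$out_channels), beta = rep(0, spec$out_channels),
           mean = rep(0, spec$out_channels), var = rep(1, spec$out_channels)))
}

#' Forward pass of a residual block
#'
#' Computes `y = relu(F(x) + shortcut(x))` in inference mode, where `F` is
#' conv-BN-ReLU-conv-BN and the shortcut is the identity (no projection) or
#' a strided 1x1 convolution plus BN. Batch normalization uses the running
#' statistics supplied in `params`.
#'
#' @param x numeric array `[H x W x C]` or `[H x W x C x N]` with
#'   `C = spec$in_channels`.
#' @param spec a [residual_block_spec()].
#' @param params parameter list as produced by `residual_block_params()`:
#'   conv kernels `conv1`, `conv2` (and `proj` when projecting) plus BN
#'   parameter lists `bn1`, `bn2` (`proj_bn`) with `gamma`, `beta`, `mean`,
#'   `var`.
#' @return output array; spatial dimensions shrink by the stride, channel
#'   count becomes `spec$out_channels`.
#' @export
residual_block_forward <- function(x, spec, params = residual_block_params(spec)) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != spec$in_channels)
    abort_arg("input has %d channels but spec expects %d", dim(x)[3], spec$in_channels)
  bn_apply <- function(z, bn) {
    d <- dim(z)
    y <- (z - .channel_bcast(bn$mean, d)) *
      .channel_bcast(bn$gamma / sqrt(bn$var + 1e-5), d) +
      .channel_bcast(bn$beta, d)
    dim(y) <- d
    y
  }
  s <- spec$stride
  f <- conv2d_fwd_cpp(x, params$conv1, s, s, 1L, 1L)
  f <- bn_apply(f, params$bn1)
  f <- f * (f > 0)
  f <- conv2d_fwd_cpp(f, params$conv2, 1L, 1L, 1L, 1L)
  f <- bn_apply(f, params$bn2)
  sc <- if (spec$projection) {
    bn_apply(conv2d_fwd_cpp(x, params$proj, s, s, 0L, 0L), params$proj_bn)
  } else x
  if (!all(dim(f) == dim(sc))) abort_arg("shape mismatch between residual and shortcut paths")
  y <- f + sc
  y <- y * (y > 0)
  if (single) dim(y) <- dim(y)[1:3]
  y
}
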