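# Layer machinery for the two-stream network. Feature maps are numeric
# arrays laid out (H, W, C, N): H = electrode-channel axis, W = time axis,
# C = feature channels, N = batch. Every layer is a mutable environment with
# fields `params`/`grads` (named lists of arrays), `decay` (names of params
# subject to weight decay), and closures `fwd(x, training)` / `bwd(dy)`.
# Convolution and max-pooling call the compiled kernels.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list(); e$grads <- list(); e$decay <- character(0)
  e
}

# He-normal initialization, drawn from the current (seeded) RNG stream
he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

nn_conv2d <- function(c_in, c_out, kh = 3L, kw = 3L,
                      stride = c(1L, 1L), pad = c(1L, 1L)) {
  self <- new_layer("conv2d")
  self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$params$W <- he_init(c(kh, kw, c_in, c_out), kh * kw * c_in)
  self$decay <- "W"
  self$fwd <- function(x, training = FALSE) {
    self$x <- x
    conv2d_fwd_cpp(x, self$params$W, self$stride[1], self$stride[2],
                   self$pad[1], self$pad[2])
  }
  self$bwd <- function(dy) {
    g <- conv2d_bwd_cpp(self$x, self$params$W, dy,
                        self$stride[1], self$stride[2],
                        self$pad[1], self$pad[2])
    self$grads$W <- g$dW
    self$x <- NULL
    g$dx
  }
  self
}

# per-feature-channel sums of an (H, W, C, N) array
.channel_sum <- function(x, d) {
  cs <- colSums(matrix(x, nrow = d[1] * d[2]))        # over H, W -> (C*N)
  rowSums(matrix(cs, d[3], d[4]))                     # over N    -> (C)
}

# broadcast a length-C vector over (H, W, C, N); the length-(H*W*C) result
# recycles cleanly over the batch axis in elementwise arithmetic
.channel_bcast <- function(v, d) rep(v, each = d[1] * d[2])

nn_batchnorm <- function(c_feat, momentum = 0.5, eps = 1e-5) {
  self <- new_layer("batchnorm")
  self$params$gamma <- rep(1, c_feat)
  self$params$beta <- rep(0, c_feat)
  self$running_mean <- rep(0, c_feat)
  self$running_var <- rep(1, c_feat)
  self$momentum <- momentum; self$eps <- eps
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x); m <- d[1] * d[2] * d[4]
    if (training) {
      mu <- .channel_sum(x, d) / m
      v <- .channel_sum(x^2, d) / m - mu^2
      v[v < 0] <- 0
      self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * v
    } else {
      mu <- self$running_mean; v <- self$running_var
    }
    inv_std <- 1 / sqrt(v + self$eps)
    xh <- (x - .channel_bcast(mu, d)) * .channel_bcast(inv_std, d)
    dim(xh) <- d
    if (training) { self$xh <- xh; self$inv_std <- inv_std; self$d <- d }
    y <- xh * .channel_bcast(self$params$gamma, d) + .channel_bcast(self$params$beta, d)
    dim(y) <- d
    y
  }
  self$bwd <- function(dy) {
    d <- self$d; m <- d[1] * d[2] * d[4]
    dgamma <- .channel_sum(dy * self$xh, d)
    dbeta <- .channel_sum(dy, d)
    self$grads$gamma <- dgamma
    self$grads$beta <- dbeta
    coef <- .channel_bcast(self$params$gamma * self$inv_std, d)
    dx <- coef * (dy - .channel_bcast(dbeta / m, d) -
                    self$xh * .channel_bcast(dgamma / m, d))
    dim(dx) <- d
    self$xh <- NULL
    dx
  }
  self
}

nn_relu <- function() {
  self <- new_layer("relu")
  self$fwd <- function(x, training = FALSE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$bwd <- function(dy) {
    dx <- dy * self$mask
    self$mask <- NULL
    dx
  }
  self
}

nn_maxpool <- function(kh, kw, stride, pad = c(0L, 0L)) {
  self <- new_layer("maxpool")
  self$k <- as.integer(c(kh, kw)); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$fwd <- function(x, training = FALSE) {
    self$xdim <- dim(x)
    r <- maxpool_fwd_cpp(x, self$k[1], self$k[2], self$stride[1],
                         self$stride[2], self$pad[1], self$pad[2])
    self$argmax <- r$argmax
    r$y
  }
  self$bwd <- function(dy) {
    dx <- maxpool_bwd_cpp(dy, self$argmax, self$xdim)
    self$argmax <- NULL
    dx
  }
  self
}

nn_gap <- function() {
  self <- new_layer("gap")
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x); self$d <- d
    matrix(colSums(matrix(x, nrow = d[1] * d[2])) / (d[1] * d[2]), d[3], d[4])
  }
  self$bwd <- function(dy) {
    d <- self$d
    dx <- rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2])
    dim(dx) <- d
    dx
  }
  self
}

# shared ECA math: 1-D convolution of the pooled channel vector (C x N)
# with a single length-k kernel, symmetric zero padding, then sigmoid
.eca_conv <- function(p, w) {
  k <- length(w); h <- (k - 1L) %/% 2L
  C <- nrow(p); N <- ncol(p)
  P0 <- rbind(matrix(0, h, N), p, matrix(0, h, N))
  s <- matrix(0, C, N)
  for (j in seq_len(k)) s <- s + w[j] * P0[j:(j + C - 1L), , drop = FALSE]
  list(s = s, P0 = P0)
}

nn_eca <- function(c_feat, gamma = 2L, lam = 1L) {
  self <- new_layer("eca")
  self$k <- eca_kernel_size(c_feat, gamma, lam)
  self$params$w <- rnorm(self$k, sd = 0.1)
  self$fwd <- function(p, training = FALSE) {
    cv <- .eca_conv(p, self$params$w)
    omega <- 1 / (1 + exp(-cv$s))
    self$p <- p; self$P0 <- cv$P0; self$omega <- omega
    omega * p
  }
  self$bwd <- function(da) {
    omega <- self$omega; p <- self$p; P0 <- self$P0
    k <- self$k; h <- (k - 1L) %/% 2L; C <- nrow(p); N <- ncol(p)
    ds <- da * p * omega * (1 - omega)
    dw <- numeric(k)
    dP0 <- matrix(0, C + 2L * h, N)
    for (j in seq_len(k)) {
      rows <- j:(j + C - 1L)
      dw[j] <- sum(P0[rows, , drop = FALSE] * ds)
      dP0[rows, ] <- dP0[rows, , drop = FALSE] + self$params$w[j] * ds
    }
    self$grads$w <- dw
    dp <- da * omega + dP0[(h + 1L):(h + C), , drop = FALSE]
    self$p <- NULL; self$P0 <- NULL; self$omega <- NULL
    dp
  }
  self
}

nn_dense <- function(n_in, n_out) {
  self <- new_layer("dense")
  self$params$W <- he_init(c(n_in, n_out), n_in)
  self$params$b <- rep(0, n_out)
  self$decay <- "W"
  self$fwd <- function(x, training = FALSE) {  # x: (n_in x N)
    self$x <- x
    crossprod(self$params$W, x) + self$params$b
  }
  self$bwd <- function(dy) {
    self$grads$W <- self$x %*% t(dy)
    self$grads$b <- rowSums(dy)
    dx <- self$params$W %*% dy
    self$x <- NULL
    dx
  }
  self
}

nn_dropout <- function(rate = 0.5) {
  self <- new_layer("dropout")
  self$rate <- rate
  self$fwd <- function(x, training = FALSE) {
    if (!training || self$rate <= 0) return(x)
    self$mask <- (runif(length(x)) >= self$rate) / (1 - self$rate)
    x * self$mask
  }
  self$bwd <- function(dy) {
    if (is.null(self$mask)) return(dy)
    dx <- dy * self$mask
    self$mask <- NULL
    dx
  }
  self
}

# residual block: conv-BN-ReLU-conv-BN + shortcut, ReLU after the sum.
# Identity shortcut when shape is preserved, 1x1 strided projection + BN
# otherwise; the additive shortcut keeps the block's input gradient at
# identity when the residual path is null.
nn_resblock <- function(c_in, c_out, stride = c(1L, 1L)) {
  self <- new_layer("resblock")
  stride <- as.integer(stride)
  self$projection <- !(all(stride == 1L) && c_in == c_out)
  self$conv1 <- nn_conv2d(c_in, c_out, 3L, 3L, stride = stride)
  self$bn1 <- nn_batchnorm(c_out)
  self$relu1 <- nn_relu()
  self$conv2 <- nn_conv2d(c_out, c_out, 3L, 3L)
  self$bn2 <- nn_batchnorm(c_out)
  self$relu_out <- nn_relu()
  if (self$projection) {
    self$proj <- nn_conv2d(c_in, c_out, 1L, 1L, stride = stride, pad = c(0L, 0L))
    self$proj_bn <- nn_batchnorm(c_out)
  }
  self$fwd <- function(x, training = FALSE) {
    f <- self$bn2$fwd(self$conv2$fwd(
      self$relu1$fwd(self$bn1$fwd(self$conv1$fwd(x, training), training), training),
      training), training)
    sc <- if (self$projection)
      self$proj_bn$fwd(self$proj$fwd(x, training), training) else x
    self$relu_out$fwd(f + sc, training)
  }
  self$bwd <- function(dy) {
    dsum <- self$relu_out$bwd(dy)
    df <- self$conv1$bwd(self$bn1$bwd(self$relu1$bwd(
      self$conv2$bwd(self$bn2$bwd(dsum)))))
    dsc <- if (self$projection) self$proj$bwd(self$proj_bn$bwd(dsum)) else dsum
    df + dsc
  }
  self$children <- function() {
    kids <- list(self$conv1, self$bn1, self$conv2, self$bn2)
    if (self$projection) kids <- c(kids, list(self$proj, self$proj_bn))
    kids
  }
  self
}

# flatten a layer tree into the list of parameter-holding leaf layers
collect_layers <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$children)) return(unlist(lapply(x$children(), collect_layers)))
    if (length(x$params) > 0 || x$type %in% c("batchnorm")) return(list(x))
    return(list())
  }
  unlist(lapply(x, collect_layers))
}
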