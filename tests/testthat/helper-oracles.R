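# Independent brute-force oracles the vectorized/compiled implementations
# are checked against. All are deliberately written as plain loops.

naive_conv2d <- function(x, w, stride = c(1L, 1L), pad = c(1L, 1L)) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Hout <- (H + 2 * pad[1] - kh) %/% stride[1] + 1L
  Wout <- (W + 2 * pad[2] - kw) %/% stride[2] + 1L
  y <- array(0, c(Hout, Wout, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (jo in 1:Wout) for (io in 1:Hout) {
    s <- 0
    for (ci in 1:C) for (b in 1:kw) for (a in 1:kh) {
      ii <- (io - 1L) * stride[1] + a - pad[1]
      jj <- (jo - 1L) * stride[2] + b - pad[2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj, ci, n] * w[a, b, ci, co]
    }
    y[io, jo, co, n] <- s
  }
  y
}

naive_bn <- function(x, gamma, beta, mu, v, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3]))
    y[, , c, ] <- (x[, , c, ] - mu[c]) / sqrt(v[c] + eps) * gamma[c] + beta[c]
  y
}

naive_gap <- function(fm) {
  d <- dim(fm)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + fm[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

# sliding dot product with symmetric zero padding + sigmoid, one vector
naive_eca <- function(pooled, w) {
  k <- length(w); h <- (k - 1) %/% 2; C <- length(pooled)
  padded <- c(rep(0, h), pooled, rep(0, h))
  s <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (j in seq_len(k)) acc <- acc + w[j] * padded[c + j - 1]
    s[c] <- acc
  }
  omega <- 1 / (1 + exp(-s))
  list(weights = omega, attended = omega * pooled)
}

# expected window count from an explicit offset loop
naive_window_count <- function(n, L, Ld) {
  count <- 0L
  offset <- 0L
  while (offset + L <= n) {
    count <- count + 1L
    offset <- offset + Ld
  }
  count
}

naive_cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  total <- 0
  for (i in seq_len(nrow(y_true))) {
    s <- 0
    for (j in seq_len(ncol(y_true)))
      s <- s - y_true[i, j] * log(max(y_pred[i, j], eps))
    total <- total + s
  }
  total / nrow(y_true)
}

naive_confusion <- function(pred, truth, k) {
  m <- matrix(0L, k, k)
  for (i in seq_along(pred))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  m
}
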