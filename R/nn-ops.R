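# Low-level numeric kernels for the transformer autoencoder.
# Everything here works on plain matrices; batches of sequences are stored
# row-flattened as (n * L) x D with one contiguous block of L rows per
# sequence. All backward functions return exact analytic gradients; they
# are validated against finite differences in the test suite.

.addBias <- function(X, b) sweep(X, 2L, b, "+")

.linearFwd <- function(X, W, b) .addBias(X %*% W, b)

.linearBwd <- function(dY, X, W) {
  list(dX = dY %*% t(W),
       dW = crossprod(X, dY),
       db = colSums(dY))
}

.reluFwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

.reluBwd <- function(dY, mask) dY * mask

.LN_EPS <- 1e-5

# row-wise layer normalization with learned gain/offset
.layerNormFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  Y <- .addBias(sweep(xhat, 2L, g, "*"), b)
  list(Y = Y, xhat = xhat, inv = inv)
}

.layerNormBwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX,
       dg = colSums(dY * xhat),
       db = colSums(dY))
}

# numerically stable row-wise softmax
.softmaxRows <- function(X) {
  m <- apply(X, 1L, max)
  e <- exp(X - m)
  e / rowSums(e)
}

# inverted dropout; returns scaled activations and the mask used
.dropoutFwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(X), 1L, keep), nrow = nrow(X)) / keep
  list(Y = X * mask, mask = mask)
}

.dropoutBwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# sinusoidal positional encodings, L x D
.positionalEncoding <- function(L, D) {
  pos <- seq_len(L) - 1L
  P <- matrix(0, L, D)
  for (j in seq_len(ceiling(D / 2))) {
    freq <- 1 / (10000^((2 * (j - 1)) / D))
    P[, 2L * j - 1L] <- sin(pos * freq)
    if (2L * j <= D) P[, 2L * j] <- cos(pos * freq)
  }
  P
}

# shift the L-row block of every sequence by `offset` positions:
# output position t reads input position t + offset; out-of-range rows are 0
.shiftBlocks <- function(X, offset, L, n) {
  if (offset == 0L) return(X)
  out <- matrix(0, nrow(X), ncol(X))
  tt <- seq_len(L)
  src <- tt + offset
  ok <- src >= 1L & src <= L
  if (!any(ok)) return(out)
  base <- rep((seq_len(n) - 1L) * L, each = sum(ok))
  out[base + tt[ok], ] <- X[base + src[ok], ]
  out
}

# squared L2 norm over an arbitrarily nested list of numeric arrays
.gradSqNorm <- function(g) {
  if (is.list(g)) sum(vapply(g, .gradSqNorm, numeric(1)))
  else sum(g * g)
}

.scaleGrads <- function(g, s) {
  if (is.list(g)) lapply(g, .scaleGrads, s = s) else g * s
}

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike) else array(0, dim = dim(p) %||% length(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one Adam step over a nested parameter list; state carries m, v, t
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      upd <- Map(walk, p, g, m, v)
      list(p = lapply(upd, `[[`, "p"),
           m = lapply(upd, `[[`, "m"),
           v = lapply(upd, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  upd <- walk(params, grads, state$m, state$v)
  list(params = upd$p,
       state = list(m = upd$m, v = upd$v, t = state$t))
}

.glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}
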