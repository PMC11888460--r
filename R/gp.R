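# Exact Gaussian-process regression surrogate for the latent-space
# Bayesian-optimization loop: isotropic RBF kernel, hyperparameters
# (length-scale, signal variance, noise variance) fitted by maximizing the
# log marginal likelihood, Cholesky-based posterior.

.sqDistMat <- function(A, B) {
  sqA <- rowSums(A * A); sqB <- rowSums(B * B)
  D2 <- outer(sqA, sqB, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

.gpKernel <- function(D2, ls, sf2) sf2 * exp(-D2 / (2 * ls^2))

.gpNll <- function(theta, D2, y, n) {
  ls <- exp(theta[1L]); sf2 <- exp(2 * theta[2L]); sn2 <- exp(2 * theta[3L])
  K <- .gpKernel(D2, ls, sf2) + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian-process surrogate
#'
#' Exact GP regression with an isotropic squared-exponential kernel.
#' The length-scale, signal variance and noise variance are fitted by
#' ML-II (L-BFGS-B on the log marginal likelihood); targets are centered
#' and scaled internally. If the optimizer fails, moment-based starting
#' values are kept and a warning is issued.
#'
#' @param X Observed points, one per row.
#' @param y Observed objective values.
#' @return A fitted surrogate of class `casGP`.
#' @export
gpFit <- function(X, y) {
  X <- .asLatentMatrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L, all(is.finite(X)),
            all(is.finite(y)))
  n <- nrow(X)
  yMean <- mean(y)
  ySd <- stats::sd(y)
  if (!is.finite(ySd) || ySd < 1e-12) ySd <- 1
  ys <- (y - yMean) / ySd
  D2 <- .sqDistMat(X, X)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  theta0 <- c(log(med), log(1), log(0.05))
  opt <- tryCatch(
    stats::optim(theta0, .gpNll, D2 = D2, y = ys, n = n,
                 method = "L-BFGS-B",
                 lower = c(log(med) - 6, log(1e-3), log(1e-4)),
                 upper = c(log(med) + 6, log(1e3), log(10))),
    error = function(e) NULL)
  theta <- if (!is.null(opt) && is.finite(opt$value)) opt$par else {
    warning("GP hyperparameter optimization failed; using starting values")
    theta0
  }
  ls <- exp(theta[1L]); sf2 <- exp(2 * theta[2L]); sn2 <- exp(2 * theta[3L])
  K <- .gpKernel(D2, ls, sf2) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, y = y, yMean = yMean, ySd = ySd,
                 ls = ls, sf2 = sf2, sn2 = sn2, chol = ch, alpha = alpha),
            class = "casGP")
}

#' Posterior prediction from a fitted GP surrogate
#'
#' @param fit A `casGP` from [gpFit()].
#' @param Xnew Query points, one per row (or a single vector).
#' @return A list with `mean` and `sd` (posterior standard deviation of
#'   the latent function, excluding observation noise), both on the
#'   original scale of `y`.
#' @export
gpPredict <- function(fit, Xnew) {
  stopifnot(inherits(fit, "casGP"))
  Xnew <- .asLatentMatrix(Xnew)
  Ks <- .gpKernel(.sqDistMat(Xnew, fit$X), fit$ls, fit$sf2)
  mu <- as.vector(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(fit$sf2 - colSums(v * v), 0)
  list(mean = mu * fit$ySd + fit$yMean, sd = sqrt(var) * fit$ySd)
}

#' Acquisition functions
#'
#' Expected improvement (for maximization) and upper confidence bound
#' over a GP posterior.
#'
#' @param mean,sd Posterior mean and standard deviation.
#' @param best Incumbent best observed value (EI).
#' @param kappa Exploration weight (UCB, default 2).
#' @return A numeric vector of acquisition values.
#' @export
expectedImprovement <- function(mean, sd, best) {
  out <- pmax(mean - best, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- (mean[pos] - best) / sd[pos]
    out[pos] <- (mean[pos] - best) * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  out
}

#' @rdname expectedImprovement
#' @export
upperConfidenceBound <- function(mean, sd, kappa = 2) mean + kappa * sd

# inflated bounding box of a set of points (total width scaled by 1.2)
.observedBox <- function(X) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  r <- pmax(hi - lo, 1e-6)
  list(lo = lo - 0.1 * r, hi = hi + 0.1 * r, range = r)
}

.uniformInBox <- function(m, box) {
  d <- length(box$lo)
  matrix(stats::runif(m * d, rep(box$lo, each = m), rep(box$hi, each = m)),
         m, d)
}

#' Propose the next latent vector to evaluate
#'
#' Maximizes the acquisition function over a finite candidate pool:
#' Gaussian perturbations of randomly chosen observed points plus uniform
#' draws from the observed bounding box inflated by 20%. Pool enumeration
#' is robust in moderate dimension and deterministic under the caller's
#' seed.
#'
#' @param fit A `casGP` surrogate fitted on at least 2 observations, or
#'   `NULL` (surrogate failure), in which case a uniform random point from
#'   the box around `fallbackX` is returned with a warning.
#' @param acquisition `"EI"` (default) or `"UCB"`.
#' @param ucbKappa UCB exploration weight (default 2).
#' @param poolSize Number of pool candidates (default 256).
#' @param fallbackX Observed points used only when `fit` is `NULL`.
#' @return A latent vector.
#' @export
proposeNextLatent <- function(fit, acquisition = c("EI", "UCB"),
                              ucbKappa = 2, poolSize = 256L,
                              fallbackX = NULL) {
  acquisition <- match.arg(acquisition)
  if (is.null(fit)) {
    warning("surrogate unavailable; falling back to uniform random proposal")
    box <- .observedBox(.asLatentMatrix(fallbackX))
    return(as.vector(.uniformInBox(1L, box)))
  }
  stopifnot(inherits(fit, "casGP"))
  X <- fit$X
  box <- .observedBox(X)
  nGlobal <- ceiling(poolSize / 2)
  nLocal <- poolSize - nGlobal
  pool <- .uniformInBox(nGlobal, box)
  if (nLocal > 0L) {
    anchors <- X[sample.int(nrow(X), nLocal, replace = TRUE), , drop = FALSE]
    noise <- matrix(stats::rnorm(nLocal * ncol(X)), nLocal, ncol(X)) *
      matrix(0.1 * box$range, nLocal, ncol(X), byrow = TRUE)
    pool <- rbind(pool, anchors + noise)
  }
  post <- gpPredict(fit, pool)
  acq <- if (acquisition == "EI")
    expectedImprovement(post$mean, post$sd, max(fit$y))
  else upperConfidenceBound(post$mean, post$sd, ucbKappa)
  pool[which.max(acq), ]
}
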