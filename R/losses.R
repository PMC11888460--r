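# Loss components of the regularized autoencoder: classification
# cross-entropy (optionally class-weighted), intra/inter-class latent
# distances and the weighted margin loss, per-position reconstruction
# cross-entropy, and their weighted total.

.CLAMP <- 1e-12

#' Margin-loss weights
#'
#' @param wCas,wNonCas Nonnegative weights on the intra-class compactness
#'   of Cas and non-Cas latents (defaults 1).
#' @param wInter Nonnegative weight on inter-class separation (default 1).
#' @param interCap Optional hinge cap: when set, the separation term
#'   `-wInter * dInter` is replaced by `wInter * max(0, interCap -
#'   dInter)`, which bounds the loss below once the classes are
#'   `interCap` apart. The default (`NULL`) keeps the plain weighted
#'   difference, which is unbounded below; training then relies on
#'   gradient clipping.
#' @return A validated named list.
#' @export
marginWeights <- function(wCas = 1, wNonCas = 1, wInter = 1,
                          interCap = NULL) {
  stopifnot(wCas >= 0, wNonCas >= 0, wInter >= 0,
            is.null(interCap) || interCap > 0)
  list(wCas = wCas, wNonCas = wNonCas, wInter = wInter,
       interCap = interCap)
}

#' Total-loss weights
#'
#' @param alpha Weight on the reconstruction loss (default 1).
#' @param beta Weight on the classification cross-entropy (default 1).
#' @param gamma Weight on the margin loss (default 1).
#' @return A validated named list.
#' @export
lossWeights <- function(alpha = 1, beta = 1, gamma = 1) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("loss weights must be nonnegative")
  list(alpha = alpha, beta = beta, gamma = gamma)
}

.trueClassProb <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  stopifnot(ncol(probabilities) == 2L,
            length(labels) == nrow(probabilities),
            all(labels %in% c(0L, 1L)))
  # column 1 = Cas (label 1), column 2 = non-Cas (label 0)
  ifelse(labels == 1L, probabilities[, 1L], probabilities[, 2L])
}

#' Classification cross-entropy
#'
#' Mean over samples of the negative log probability assigned to the true
#' class. With `classWeights` supplied, each sample's term is multiplied
#' by its true-class weight and the sum is normalized by the total applied
#' weight, so balanced data reduce to the unweighted mean.
#'
#' @param probabilities An `n x 2` matrix of class probabilities, columns
#'   `(cas, noncas)`, rows summing to 1.
#' @param labels Integer vector, 1 = Cas, 0 = non-Cas.
#' @param classWeights Optional numeric pair `c(cas, noncas)`, e.g. from
#'   [classWeightsFromCounts()].
#' @return A nonnegative scalar.
#' @examples
#' classificationLoss(matrix(c(0.5, 0.5), 1), labels = 1L)  # -log(0.5)
#' @export
classificationLoss <- function(probabilities, labels, classWeights = NULL) {
  p <- .trueClassProb(probabilities, labels)
  if (any(p <= 0)) {
    warning("true-class probability of 0 clamped at 1e-12")
    p <- pmax(p, .CLAMP)
  }
  nll <- -log(p)
  if (is.null(classWeights)) return(mean(nll))
  stopifnot(length(classWeights) == 2L, all(classWeights >= 0))
  w <- ifelse(labels == 1L, classWeights[[1L]], classWeights[[2L]])
  sum(w * nll) / sum(w)
}

#' Inverse-frequency class weights
#'
#' `weight_j = n_total / (K * count_j)` with `K = 2` classes, so the rarer
#' class is up-weighted and balanced counts give unit weights.
#'
#' @param counts Numeric pair of per-class counts `c(cas, noncas)`, both
#'   at least 1.
#' @return A named numeric pair `c(cas, noncas)`.
#' @examples
#' classWeightsFromCounts(c(cas = 100, noncas = 100))
#' @export
classWeightsFromCounts <- function(counts) {
  stopifnot(length(counts) == 2L)
  if (any(counts < 1)) stop("both class counts must be >= 1")
  w <- sum(counts) / (2 * counts)
  names(w) <- c("cas", "noncas")
  w
}

.asLatentMatrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  as.matrix(x)
}

#' Mean squared pairwise distance within a class
#'
#' Mean over all unordered pairs of the squared Euclidean distance; the
#' compactness term of the margin loss. Defined as 0 for fewer than two
#' vectors (a single point has no spread and the pair count would divide
#' by zero).
#'
#' @param latents A matrix with one latent vector per row (possibly with
#'   0 or 1 rows).
#' @return A nonnegative scalar.
#' @export
intraClassDistance <- function(latents) {
  X <- .asLatentMatrix(latents)
  m <- nrow(X)
  if (m < 2L) return(0)
  sq <- rowSums(X * X)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  sum(D2[upper.tri(D2)]) / choose(m, 2L)
}

#' Mean squared pairwise distance between two classes
#'
#' Mean over all cross-class pairs of the squared Euclidean distance; the
#' separation term of the margin loss.
#'
#' @param casLatents,nonCasLatents Matrices with one latent per row; both
#'   must be nonempty.
#' @return A nonnegative scalar.
#' @export
interClassDistance <- function(casLatents, nonCasLatents) {
  A <- .asLatentMatrix(casLatents)
  B <- .asLatentMatrix(nonCasLatents)
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("both classes must be nonempty; skip the inter term instead")
  if (ncol(A) != ncol(B)) stop("latent dimensions differ between classes")
  sqA <- rowSums(A * A)
  sqB <- rowSums(B * B)
  D2 <- outer(sqA, sqB, "+") - 2 * tcrossprod(A, B)
  mean(D2)
}

#' Weighted max-margin latent loss
#'
#' `wCas * dCas + wNonCas * dNonCas - wInter * dInter`, rewarding compact
#' same-class clusters and separated class clouds. If a class is absent
#' from the batch the inter-class term is 0 and a warning is issued (its
#' intra term is 0 as well).
#'
#' @param latents Matrix with one latent per row.
#' @param labels Integer vector, 1 = Cas, 0 = non-Cas.
#' @param weights A [marginWeights()] list.
#' @return A scalar (may be negative: separation is unbounded).
#' @export
marginLoss <- function(latents, labels, weights = marginWeights()) {
  X <- .asLatentMatrix(latents)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(0L, 1L)))
  if (nrow(X) == 0L) stop("empty batch")
  cas <- X[labels == 1L, , drop = FALSE]
  non <- X[labels == 0L, , drop = FALSE]
  dCas <- intraClassDistance(cas)
  dNon <- intraClassDistance(non)
  intra <- weights$wCas * dCas + weights$wNonCas * dNon
  if (nrow(cas) == 0L || nrow(non) == 0L) {
    warning("one class absent from batch; inter-class term set to 0")
    return(intra)
  }
  dInter <- interClassDistance(cas, non)
  if (is.null(weights$interCap))
    intra - weights$wInter * dInter
  else
    intra + weights$wInter * max(0, weights$interCap - dInter)
}

# analytic gradient of the margin loss w.r.t. every latent row
.marginLossGrad <- function(latents, labels, weights = marginWeights()) {
  X <- .asLatentMatrix(latents)
  G <- matrix(0, nrow(X), ncol(X))
  iCas <- which(labels == 1L)
  iNon <- which(labels == 0L)
  m1 <- length(iCas); m2 <- length(iNon)
  # d/dXi of (1/C(m,2)) sum_{i<j} ||Xi-Xj||^2 = (2/C(m,2)) (m Xi - sum X)
  if (m1 >= 2L)
    G[iCas, ] <- G[iCas, ] + weights$wCas * (2 / choose(m1, 2L)) *
      (m1 * X[iCas, , drop = FALSE] -
         matrix(colSums(X[iCas, , drop = FALSE]), m1, ncol(X), byrow = TRUE))
  if (m2 >= 2L)
    G[iNon, ] <- G[iNon, ] + weights$wNonCas * (2 / choose(m2, 2L)) *
      (m2 * X[iNon, , drop = FALSE] -
         matrix(colSums(X[iNon, , drop = FALSE]), m2, ncol(X), byrow = TRUE))
  interActive <- m1 >= 1L && m2 >= 1L
  if (interActive && !is.null(weights$interCap)) {
    dInter <- interClassDistance(X[iCas, , drop = FALSE],
                                 X[iNon, , drop = FALSE])
    interActive <- dInter < weights$interCap   # hinge: flat once separated
  }
  if (interActive) {
    sCas <- colSums(X[iCas, , drop = FALSE])
    sNon <- colSums(X[iNon, , drop = FALSE])
    G[iCas, ] <- G[iCas, ] - weights$wInter * (2 / (m1 * m2)) *
      (m2 * X[iCas, , drop = FALSE] - matrix(sNon, m1, ncol(X), byrow = TRUE))
    G[iNon, ] <- G[iNon, ] - weights$wInter * (2 / (m1 * m2)) *
      (m1 * X[iNon, , drop = FALSE] - matrix(sCas, m2, ncol(X), byrow = TRUE))
  }
  G
}

# positions counted by the masked reconstruction loss: everything up to and
# including the end token (or up to the first pad when no end token exists)
.countedPositions <- function(targetRow) {
  endAt <- which(targetRow == 2L)
  if (length(endAt) > 0L) return(seq_len(endAt[1L]))
  padAt <- which(targetRow == 0L)
  if (length(padAt) > 0L) {
    if (padAt[1L] == 1L) return(integer(0))
    return(seq_len(padAt[1L] - 1L))
  }
  seq_along(targetRow)
}

.stackLogits <- function(predictions, n, L) {
  if (is.list(predictions)) {
    stopifnot(length(predictions) == n)
    do.call(rbind, predictions)
  } else if (is.matrix(predictions) && n == 1L && nrow(predictions) == L) {
    predictions
  } else if (is.matrix(predictions) && nrow(predictions) == n * L) {
    predictions
  } else stop("predictions must be a list of maxLen x 24 logit matrices")
}

#' Per-position reconstruction cross-entropy
#'
#' Mean over counted positions of the negative log probability assigned to
#' the true token, after row-wise softmax of the logits. With
#' `maskPadding = TRUE` (default) only positions up to and including the
#' end token are counted, so the decoder is not rewarded for predicting
#' padding; with `maskPadding = FALSE` all positions count.
#'
#' @param targets Integer token matrix (one row per sequence) as produced
#'   by [encodeSequences()].
#' @param predictions A list of per-sequence `maxLen x 24` logit matrices
#'   (as returned by [decodeFromLatent()]), a single such matrix for one
#'   sequence, or a row-stacked `(n*maxLen) x 24` matrix.
#' @param maskPadding Logical (default `TRUE`).
#' @return A nonnegative scalar.
#' @export
reconstructionLoss <- function(targets, predictions, maskPadding = TRUE) {
  if (is.vector(targets)) targets <- matrix(as.integer(targets), nrow = 1L)
  n <- nrow(targets); L <- ncol(targets)
  logits <- .stackLogits(predictions, n, L)
  stopifnot(ncol(logits) == 24L, nrow(logits) == n * L)
  P <- .softmaxRows(logits)
  total <- 0; count <- 0L; clamped <- FALSE
  for (s in seq_len(n)) {
    pos <- if (maskPadding) .countedPositions(targets[s, ]) else seq_len(L)
    if (length(pos) == 0L) next
    rows <- (s - 1L) * L + pos
    p <- P[cbind(rows, targets[s, pos] + 1L)]
    if (any(p <= 0)) { clamped <- TRUE; p <- pmax(p, .CLAMP) }
    total <- total - sum(log(p))
    count <- count + length(pos)
  }
  if (clamped) warning("true-token probability of 0 clamped at 1e-12")
  if (count == 0L) return(0)
  total / count
}

#' Weighted total loss
#'
#' `total = alpha * recon + beta * classification + gamma * margin`.
#'
#' @param recon,classification,margin The three loss components.
#' @param weights A [lossWeights()] list.
#' @return A named numeric vector with elements `recon`,
#'   `classification`, `margin`, `total` (a loss breakdown).
#' @export
totalLoss <- function(recon, classification, margin,
                      weights = lossWeights()) {
  c(recon = recon, classification = classification, margin = margin,
    total = weights$alpha * recon + weights$beta * classification +
      weights$gamma * margin)
}
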