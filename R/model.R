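#' Model configuration for the regularized transformer autoencoder
#'
#' Bundles the architecture hyperparameters of the model: a transformer
#' encoder (multi-head self-attention + feed-forward blocks with residual
#' connections and layer normalization) that maps a tokenized protein to a
#' d-dimensional latent vector by pad-masked mean pooling, a 1-D
#' convolutional decoder that expands the latent vector back to
#' per-position token logits, and a two-layer perceptron classifier head
#' that separates Cas from non-Cas latents.
#'
#' @param latentDim Latent dimensionality d (default 32).
#' @param encoderLayers Number of transformer encoder blocks (default 4).
#' @param attentionHeads Attention heads per block (default 4); must divide
#'   `modelWidth`.
#' @param modelWidth Embedding/model width (default 128).
#' @param feedforwardWidth Hidden width of each block's feed-forward
#'   network (default 256).
#' @param dropoutRate Dropout rate in `[0, 1)` applied inside encoder
#'   blocks during training (default 0.1).
#' @param maxLen Fixed tokenized length including start/end tokens
#'   (default 1600, sized so every curated Cas sequence fits).
#' @param decoderConvLayers Number of 1-D convolutions (kernel 5,
#'   same-padding) in the decoder (default 3).
#' @param decoderChannels Channel width of the decoder grid (default 64).
#' @param pooling How per-token encoder outputs become the latent vector:
#'   `"mean"` (pad-masked mean, default) or `"start"` (start-token state).
#' @param rngSeed Seed used to draw the initial weights (default 1).
#' @return A validated `CasModelConfig` list.
#' @export
casModelConfig <- function(latentDim = 32L, encoderLayers = 4L,
                           attentionHeads = 4L, modelWidth = 128L,
                           feedforwardWidth = 256L, dropoutRate = 0.1,
                           maxLen = 1600L, decoderConvLayers = 3L,
                           decoderChannels = 64L,
                           pooling = c("mean", "start"), rngSeed = 1L) {
  pooling <- match.arg(pooling)
  cfg <- list(latentDim = as.integer(latentDim),
              encoderLayers = as.integer(encoderLayers),
              attentionHeads = as.integer(attentionHeads),
              modelWidth = as.integer(modelWidth),
              feedforwardWidth = as.integer(feedforwardWidth),
              dropoutRate = as.numeric(dropoutRate),
              maxLen = as.integer(maxLen),
              vocabSize = 24L,
              decoderConvLayers = as.integer(decoderConvLayers),
              decoderChannels = as.integer(decoderChannels),
              pooling = pooling,
              rngSeed = as.integer(rngSeed))
  stopifnot(cfg$latentDim >= 1L, cfg$encoderLayers >= 1L,
            cfg$attentionHeads >= 1L, cfg$modelWidth >= 2L,
            cfg$feedforwardWidth >= 1L, cfg$maxLen >= 3L,
            cfg$decoderConvLayers >= 1L, cfg$decoderChannels >= 2L,
            cfg$dropoutRate >= 0, cfg$dropoutRate < 1)
  if (cfg$modelWidth %% cfg$attentionHeads != 0L)
    stop("modelWidth must be divisible by attentionHeads")
  class(cfg) <- "CasModelConfig"
  cfg
}

#' @export
print.CasModelConfig <- function(x, ...) {
  cat(sprintf(paste0("CasModelConfig: d=%d, %d encoder layer(s) ",
                     "(width %d, %d heads, ff %d), decoder %d conv ",
                     "layer(s) x %d channels, maxLen=%d, dropout=%.2f, ",
                     "pooling=%s, seed=%d\n"),
              x$latentDim, x$encoderLayers, x$modelWidth,
              x$attentionHeads, x$feedforwardWidth,
              x$decoderConvLayers, x$decoderChannels, x$maxLen,
              x$dropoutRate, x$pooling, x$rngSeed))
  invisible(x)
}

#' Regularized transformer autoencoder model
#'
#' S4 container for the model: its configuration, its weights, the fixed
#' positional encodings, the training history, and (after training) the
#' eval-mode latent coordinates of the training data, which seed the
#' Bayesian-optimization generative loop.
#'
#' @slot config A `CasModelConfig` list.
#' @slot params Nested list of weight matrices/arrays.
#' @slot posenc Sinusoidal positional-encoding matrix (maxLen x width).
#' @slot history Per-epoch training diagnostics (`data.frame`).
#' @slot trainLatents Eval-mode latents of the training set (matrix).
#' @slot trainLabels Integer class labels (1 = Cas, 0 = non-Cas) aligned
#'   with `trainLatents` rows.
#' @slot trained Logical flag.
#' @export
setOldClass("CasModelConfig")
setClass("CasModel",
         representation(config = "CasModelConfig", params = "list",
                        posenc = "matrix", history = "data.frame",
                        trainLatents = "matrix", trainLabels = "integer",
                        trained = "logical"))

setValidity("CasModel", function(object) {
  cfg <- object@config
  if (!inherits(cfg, "CasModelConfig")) return("config is not a CasModelConfig")
  if (cfg$vocabSize != 24L) return("vocabSize must be 24")
  if (nrow(object@posenc) != cfg$maxLen) return("posenc rows != maxLen")
  TRUE
})

#' @describeIn CasModel Initialize an untrained model with seeded random
#'   weights.
#' @param config A `CasModelConfig`.
#' @export
initCasModel <- function(config = casModelConfig()) {
  stopifnot(inherits(config, "CasModelConfig"))
  D <- config$modelWidth; Fw <- config$feedforwardWidth
  d <- config$latentDim; L <- config$maxLen; C <- config$decoderChannels
  set.seed(config$rngSeed)
  layer <- function() list(
    Wq = .glorot(D, D), bq = numeric(D),
    Wk = .glorot(D, D), bk = numeric(D),
    Wv = .glorot(D, D), bv = numeric(D),
    Wo = .glorot(D, D), bo = numeric(D),
    ln1g = rep(1, D), ln1b = numeric(D),
    W1 = .glorot(D, Fw), b1 = numeric(Fw),
    W2 = .glorot(Fw, D), b2 = numeric(D),
    ln2g = rep(1, D), ln2b = numeric(D))
  convs <- vector("list", config$decoderConvLayers)
  for (i in seq_along(convs))
    convs[[i]] <- list(W = array(stats::rnorm(5 * C * C, sd = sqrt(2 / (5 * C + C))),
                                 dim = c(5L, C, C)),
                       b = numeric(C))
  params <- list(
    emb = .glorot(24L, D),
    layers = lapply(seq_len(config$encoderLayers), function(i) layer()),
    Wlat = .glorot(D, d), blat = numeric(d),
    dec = list(Wexp = .glorot(d, L * C), bexp = numeric(L * C),
               convs = convs,
               Wout = .glorot(C, 24L), bout = numeric(24L)),
    cls = list(W1 = .glorot(d, d), b1 = numeric(d),
               W2 = .glorot(d, 2L), b2 = numeric(2L)))
  methods::new("CasModel", config = config, params = params,
               posenc = .positionalEncoding(L, D),
               history = data.frame(),
               trainLatents = matrix(0, 0L, d), trainLabels = integer(0),
               trained = FALSE)
}

setMethod("show", "CasModel", function(object) {
  cfg <- object@config
  cat("CasModel:", if (object@trained) "trained" else "untrained", "\n")
  print(cfg)
  if (nrow(object@history) > 0L) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  %d epoch(s); final val accuracy %.3f, silhouette %.3f\n",
                nrow(object@history), last$valAccuracy, last$valSilhouette))
  }
  if (nrow(object@trainLatents) > 0L)
    cat(sprintf("  %d stored training latents (%d Cas / %d non-Cas)\n",
                nrow(object@trainLatents), sum(object@trainLabels == 1L),
                sum(object@trainLabels == 0L)))
})

#' @describeIn CasModel Accessor for the model configuration.
#' @param model A `CasModel`.
#' @export
modelConfig <- function(model) model@config

#' @describeIn CasModel Accessor for the per-epoch training history.
#' @export
trainingHistory <- function(model) model@history

#' @describeIn CasModel Accessor for the stored training-set latents and
#'   labels (a list with elements `latents` and `labels`).
#' @export
trainingLatents <- function(model) {
  list(latents = model@trainLatents, labels = model@trainLabels)
}

.checkTokens <- function(tokens, maxLen) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1L)
  storage.mode(tokens) <- "integer"
  if (ncol(tokens) > maxLen)
    stop(sprintf("token matrix has %d columns but the model expects at most maxLen=%d",
                 ncol(tokens), maxLen))
  if (ncol(tokens) < 3L) stop("token matrix must have at least 3 columns")
  if (any(tokens < 0L | tokens > 23L)) stop("token code out of range 0..23")
  tokens
}

# ---- encoder ---------------------------------------------------------------

.encForward <- function(params, posenc, cfg, tokens, training = FALSE) {
  n <- nrow(tokens); L <- ncol(tokens); D <- cfg$modelWidth
  H <- cfg$attentionHeads; dh <- D %/% H
  idx <- as.vector(t(tokens)) + 1L              # row (s-1)L+t <-> tokens[s,t]
  X <- params$emb[idx, , drop = FALSE] + posenc[rep(seq_len(L), n), ]
  d0 <- .dropoutFwd(X, cfg$dropoutRate, training)
  X <- d0$Y
  nonpad <- tokens != 0L
  caches <- vector("list", cfg$encoderLayers)
  for (l in seq_len(cfg$encoderLayers)) {
    p <- params$layers[[l]]
    Q <- .linearFwd(X, p$Wq, p$bq)
    K <- .linearFwd(X, p$Wk, p$bk)
    V <- .linearFwd(X, p$Wv, p$bv)
    O <- matrix(0, n * L, D)
    A <- vector("list", n)
    for (s in seq_len(n)) {
      rows <- ((s - 1L) * L + 1L):(s * L)
      mask <- !nonpad[s, ]
      As <- vector("list", H)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        if (any(mask)) S[, mask] <- -Inf
        Ash <- .softmaxRows(S)
        O[rows, cols] <- Ash %*% V[rows, cols, drop = FALSE]
        As[[h]] <- Ash
      }
      A[[s]] <- As
    }
    attnOut <- .linearFwd(O, p$Wo, p$bo)
    dAttn <- .dropoutFwd(attnOut, cfg$dropoutRate, training)
    ln1 <- .layerNormFwd(X + dAttn$Y, p$ln1g, p$ln1b)
    X1 <- ln1$Y
    r1 <- .reluFwd(.linearFwd(X1, p$W1, p$b1))
    ff <- .linearFwd(r1$Y, p$W2, p$b2)
    dFF <- .dropoutFwd(ff, cfg$dropoutRate, training)
    ln2 <- .layerNormFwd(X1 + dFF$Y, p$ln2g, p$ln2b)
    caches[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A = A, O = O,
                        doA = dAttn$mask, ln1 = ln1, X1 = X1,
                        relu = r1, Hrelu = r1$Y, doF = dFF$mask, ln2 = ln2)
    X <- ln2$Y
  }
  # pooling to latent
  if (cfg$pooling == "mean") {
    grp <- rep(seq_len(n), each = L)
    keep <- as.vector(t(nonpad))
    counts <- rowSums(nonpad)
    latpre <- rowsum(X[keep, , drop = FALSE], grp[keep]) / counts
  } else {
    latpre <- X[(seq_len(n) - 1L) * L + 1L, , drop = FALSE]
    counts <- rep(1, n)
  }
  latent <- .linearFwd(latpre, params$Wlat, params$blat)
  list(latent = latent,
       cache = list(idx = idx, d0 = d0$mask, layers = caches, Xfinal = X,
                    nonpad = nonpad, counts = counts, latpre = latpre,
                    n = n, L = L))
}

.encBackward <- function(params, posenc, cfg, cache, dLatent) {
  n <- cache$n; L <- cache$L; D <- cfg$modelWidth
  H <- cfg$attentionHeads; dh <- D %/% H
  g <- list(emb = NULL, layers = vector("list", cfg$encoderLayers),
            Wlat = crossprod(cache$latpre, dLatent),
            blat = colSums(dLatent))
  dLatpre <- dLatent %*% t(params$Wlat)
  dX <- matrix(0, n * L, D)
  if (cfg$pooling == "mean") {
    scaled <- dLatpre / cache$counts
    keep <- as.vector(t(cache$nonpad))
    grp <- rep(seq_len(n), each = L)
    dX[keep, ] <- scaled[grp[keep], , drop = FALSE]
  } else {
    dX[(seq_len(n) - 1L) * L + 1L, ] <- dLatpre
  }
  for (l in rev(seq_len(cfg$encoderLayers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    b2n <- .layerNormBwd(dX, cc$ln2, p$ln2g)
    dR2 <- b2n$dX
    dFF <- .dropoutBwd(dR2, cc$doF)
    lb2 <- .linearBwd(dFF, cc$Hrelu, p$W2)
    dHpre <- .reluBwd(lb2$dX, cc$relu$mask)
    lb1 <- .linearBwd(dHpre, cc$X1, p$W1)
    dX1 <- dR2 + lb1$dX
    b1n <- .layerNormBwd(dX1, cc$ln1, p$ln1g)
    dR1 <- b1n$dX
    dAttnOut <- .dropoutBwd(dR1, cc$doA)
    lbo <- .linearBwd(dAttnOut, cc$O, p$Wo)
    dO <- lbo$dX
    dQ <- matrix(0, n * L, D); dK <- matrix(0, n * L, D)
    dV <- matrix(0, n * L, D)
    for (s in seq_len(n)) {
      rows <- ((s - 1L) * L + 1L):(s * L)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[s]][[h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(A * dA))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dh)
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    lbq <- .linearBwd(dQ, cc$Xin, p$Wq)
    lbk <- .linearBwd(dK, cc$Xin, p$Wk)
    lbv <- .linearBwd(dV, cc$Xin, p$Wv)
    g$layers[[l]] <- list(
      Wq = lbq$dW, bq = lbq$db, Wk = lbk$dW, bk = lbk$db,
      Wv = lbv$dW, bv = lbv$db, Wo = lbo$dW, bo = lbo$db,
      ln1g = b1n$dg, ln1b = b1n$db,
      W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db,
      ln2g = b2n$dg, ln2b = b2n$db)
    dX <- dR1 + lbq$dX + lbk$dX + lbv$dX
  }
  dX <- .dropoutBwd(dX, cache$d0)
  demb <- matrix(0, 24L, D)
  agg <- rowsum(dX, cache$idx)
  demb[as.integer(rownames(agg)), ] <- agg
  g$emb <- demb
  g
}

# ---- decoder ---------------------------------------------------------------

.decForward <- function(params, cfg, latent) {
  n <- nrow(latent); L <- cfg$maxLen; C <- cfg$decoderChannels
  dec <- params$dec
  G <- .linearFwd(latent, dec$Wexp, dec$bexp)
  X0 <- matrix(as.vector(t(G)), ncol = C, byrow = TRUE)
  r0 <- .reluFwd(X0)
  X <- r0$Y
  convCache <- vector("list", length(dec$convs))
  for (i in seq_along(dec$convs)) {
    W <- dec$convs[[i]]$W
    Y <- matrix(rep(dec$convs[[i]]$b, each = n * L), n * L, C)
    for (k in 1:5)
      Y <- Y + .shiftBlocks(X, k - 3L, L, n) %*% matrix(W[k, , ], C, C)
    rc <- .reluFwd(Y)
    convCache[[i]] <- list(Xin = X, mask = rc$mask)
    X <- rc$Y
  }
  logits <- .linearFwd(X, dec$Wout, dec$bout)   # (n*L) x 24
  list(logits = logits,
       cache = list(r0mask = r0$mask, convs = convCache, Xlast = X, n = n,
                    latent = latent))
}

.decBackward <- function(params, cfg, cache, dLogits) {
  n <- cache$n; L <- cfg$maxLen; C <- cfg$decoderChannels
  dec <- params$dec
  lbo <- .linearBwd(dLogits, cache$Xlast, dec$Wout)
  dX <- lbo$dX
  g <- list(Wexp = NULL, bexp = NULL,
            convs = vector("list", length(dec$convs)),
            Wout = lbo$dW, bout = lbo$db)
  for (i in rev(seq_along(dec$convs))) {
    cc <- cache$convs[[i]]
    dY <- .reluBwd(dX, cc$mask)
    W <- dec$convs[[i]]$W
    dW <- array(0, dim = c(5L, C, C))
    dX <- matrix(0, n * L, C)
    for (k in 1:5) {
      o <- k - 3L
      Xs <- .shiftBlocks(cc$Xin, o, L, n)
      dW[k, , ] <- crossprod(Xs, dY)
      dX <- dX + .shiftBlocks(dY, -o, L, n) %*% t(matrix(W[k, , ], C, C))
    }
    g$convs[[i]] <- list(W = dW, b = colSums(dY))
  }
  dX0 <- .reluBwd(dX, cache$r0mask)
  dG <- matrix(as.vector(t(dX0)), nrow = n, byrow = TRUE)
  lbe <- .linearBwd(dG, cache$latent, dec$Wexp)
  g$Wexp <- lbe$dW
  g$bexp <- lbe$db
  list(grads = g, dLatent = lbe$dX)
}

# ---- classifier ------------------------------------------------------------

.clsForward <- function(params, latent) {
  p <- params$cls
  r <- .reluFwd(.linearFwd(latent, p$W1, p$b1))
  logits <- .linearFwd(r$Y, p$W2, p$b2)
  list(logits = logits, cache = list(H = r$Y, mask = r$mask))
}

.clsBackward <- function(params, latent, cache, dLogits) {
  p <- params$cls
  lb2 <- .linearBwd(dLogits, cache$H, p$W2)
  dH <- .reluBwd(lb2$dX, cache$mask)
  lb1 <- .linearBwd(dH, latent, p$W1)
  list(grads = list(W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db),
       dLatent = lb1$dX)
}

# ---- exported forward API --------------------------------------------------

#' Encode tokenized proteins to latent vectors
#'
#' Runs the transformer encoder and pad-masked pooling. In `"eval"` mode
#' (the default) dropout is disabled and the map is deterministic.
#'
#' @param model A `CasModel`.
#' @param tokens Integer token matrix from [encodeSequences()] (or a single
#'   token vector).
#' @param mode `"eval"` or `"train"`.
#' @return A numeric matrix with one row per sequence and `latentDim`
#'   columns.
#' @export
encodeToLatent <- function(model, tokens, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  tokens <- .checkTokens(tokens, model@config$maxLen)
  .encForward(model@params, model@posenc, model@config, tokens,
              training = (mode == "train"))$latent
}

#' Decode latent vectors to per-position token logits
#'
#' Runs the convolutional decoder. Taking the row-wise argmax of the
#' returned logits and passing it through [decodeTokens()] yields a
#' candidate amino-acid sequence (see [decodeLatentToSequence()]).
#'
#' @param model A `CasModel`.
#' @param latent A latent vector of length `latentDim`, or a matrix with
#'   one latent per row.
#' @return For a single latent, a `maxLen x 24` logit matrix; for a matrix
#'   input, a list of such matrices.
#' @export
decodeFromLatent <- function(model, latent) {
  single <- is.vector(latent)
  if (single) latent <- matrix(latent, nrow = 1L)
  if (ncol(latent) != model@config$latentDim)
    stop("latent length does not match the model's latentDim")
  if (!all(is.finite(latent))) stop("latent entries must be finite")
  out <- .decForward(model@params, model@config, latent)$logits
  L <- model@config$maxLen
  mats <- lapply(seq_len(nrow(latent)), function(s)
    out[((s - 1L) * L + 1L):(s * L), , drop = FALSE])
  if (single) mats[[1L]] else mats
}

#' Decode a latent vector straight to an amino-acid sequence
#'
#' Convenience wrapper: argmax over [decodeFromLatent()] logits, then
#' [decodeTokens()].
#'
#' @inheritParams decodeFromLatent
#' @return A character vector of decoded sequences.
#' @export
decodeLatentToSequence <- function(model, latent) {
  if (is.vector(latent)) latent <- matrix(latent, nrow = 1L)
  mats <- decodeFromLatent(model, latent)
  if (is.matrix(mats)) mats <- list(mats)
  vapply(mats, function(m) {
    codes <- max.col(m, ties.method = "first") - 1L
    suppressWarnings(decodeTokens(codes))
  }, character(1))
}

#' Classify latent vectors as Cas or non-Cas
#'
#' Applies the MLP classifier head and a softmax.
#'
#' @param model A `CasModel`.
#' @param latent A latent vector or matrix of latents (rows).
#' @return A matrix with columns `cas` and `noncas`; each row is a
#'   probability pair summing to 1.
#' @export
classifyLatent <- function(model, latent) {
  if (is.vector(latent)) latent <- matrix(latent, nrow = 1L)
  if (!all(is.finite(latent))) stop("latent entries must be finite")
  if (ncol(latent) != model@config$latentDim)
    stop("latent length does not match the model's latentDim")
  logits <- .clsForward(model@params, latent)$logits
  probs <- .softmaxRows(logits)
  colnames(probs) <- c("cas", "noncas")
  probs
}
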