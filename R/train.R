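#' Training configuration
#'
#' Hyperparameters of the seeded end-to-end training loop. The optimizer
#' is Adam with global gradient-norm clipping; clipping matters because
#' the margin loss is unbounded below, so its gradient can transiently
#' dominate.
#'
#' @param epochs Number of passes over the training split.
#' @param batchSize Mini-batch size (default 32; must be at least 2 when
#'   the margin weight `gamma > 0`).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param gradientClipNorm Global L2 clip on the gradient (default 1.0).
#' @param stratifiedBatching Mix both classes into every batch (default
#'   `TRUE`); the margin loss is degenerate on single-class batches.
#' @param valFraction Held-out fraction for validation, stratified
#'   (default 0.2).
#' @param classWeighting Apply inverse-frequency class weights to the
#'   classification loss (default `TRUE`).
#' @param loss A [lossWeights()] list (alpha, beta, gamma).
#' @param margin A [marginWeights()] list.
#' @param earlyStopping Stop when validation total loss has not improved
#'   for `patience` epochs (default `FALSE`, keeping run length
#'   deterministic).
#' @param patience Early-stopping patience (default 10).
#' @param rngSeed Seed for the split, batch shuffling and dropout.
#' @param verbose Print one line per epoch (default `FALSE`).
#' @return A validated list of class `CasTrainingConfig`.
#' @export
trainingConfig <- function(epochs = 30L, batchSize = 32L,
                           learningRate = 1e-3, gradientClipNorm = 1.0,
                           stratifiedBatching = TRUE, valFraction = 0.2,
                           classWeighting = TRUE, loss = lossWeights(),
                           margin = marginWeights(), earlyStopping = FALSE,
                           patience = 10L, rngSeed = 1L, verbose = FALSE) {
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              learningRate = learningRate,
              gradientClipNorm = gradientClipNorm,
              stratifiedBatching = isTRUE(stratifiedBatching),
              valFraction = valFraction,
              classWeighting = isTRUE(classWeighting),
              loss = loss, margin = margin,
              earlyStopping = isTRUE(earlyStopping),
              patience = as.integer(patience),
              rngSeed = as.integer(rngSeed), verbose = isTRUE(verbose))
  stopifnot(cfg$epochs >= 1L, cfg$batchSize >= 1L, cfg$learningRate > 0,
            cfg$gradientClipNorm > 0, cfg$valFraction >= 0,
            cfg$valFraction < 1)
  if (cfg$loss$gamma > 0 && cfg$batchSize < 2L)
    stop("batchSize must be >= 2 when the margin weight gamma > 0")
  class(cfg) <- "CasTrainingConfig"
  cfg
}

.normalizeLabels <- function(labels, n) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("cas", "noncas")
    if (any(bad)) stop("labels must be 'cas' or 'noncas'")
    labels <- as.integer(labels == "cas")
  }
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per sequence required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1 or cas/noncas")
  labels
}

# cyclic batch assignment per class so each batch sees both classes
.makeBatches <- function(labels, batchSize, stratified) {
  n <- length(labels)
  if (!stratified) {
    ord <- sample.int(n)
    return(split(ord, ceiling(seq_along(ord) / batchSize)))
  }
  nBatches <- max(1L, min(floor(n / batchSize),
                          sum(labels == 1L), sum(labels == 0L)))
  ids <- integer(n)
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    ids[idx] <- rep_len(seq_len(nBatches), length(idx))
  }
  split(seq_len(n), ids)
}

# forward + losses in eval mode on a (sub)set, chunked to bound memory
.evalSplit <- function(params, posenc, cfg, tokens, labels, tc, cw) {
  n <- nrow(tokens)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / max(tc$batchSize, 16L)))
  latents <- matrix(0, n, cfg$latentDim)
  reconNum <- 0; reconDen <- 0L
  probs <- matrix(0, n, 2L)
  for (ch in chunks) {
    enc <- .encForward(params, posenc, cfg, tokens[ch, , drop = FALSE],
                       training = FALSE)
    latents[ch, ] <- enc$latent
    dec <- .decForward(params, cfg, enc$latent)
    r <- .reconWithGrad(tokens[ch, , drop = FALSE], dec$logits)
    reconNum <- reconNum + r$loss * r$count
    reconDen <- reconDen + r$count
    probs[ch, ] <- .softmaxRows(.clsForward(params, enc$latent)$logits)
  }
  rownames(latents) <- rownames(tokens)
  recon <- if (reconDen > 0L) reconNum / reconDen else 0
  ce <- classificationLoss(probs, labels, cw)
  marg <- if (tc$loss$gamma > 0)
    suppressWarnings(marginLoss(latents, labels, tc$margin)) else 0
  acc <- mean((probs[, 1L] >= 0.5) == (labels == 1L))
  list(breakdown = totalLoss(recon, ce, marg, tc$loss),
       accuracy = acc, latents = latents)
}

# masked reconstruction CE plus the gradient w.r.t. the stacked logits
.reconWithGrad <- function(targets, logits, wantGrad = FALSE) {
  n <- nrow(targets); L <- ncol(targets)
  P <- .softmaxRows(logits)
  rows <- integer(0); cols <- integer(0)
  for (s in seq_len(n)) {
    pos <- .countedPositions(targets[s, ])
    rows <- c(rows, (s - 1L) * L + pos)
    cols <- c(cols, targets[s, pos] + 1L)
  }
  count <- length(rows)
  p <- pmax(P[cbind(rows, cols)], .CLAMP)
  loss <- if (count) -sum(log(p)) / count else 0
  grad <- NULL
  if (wantGrad && count) {
    grad <- matrix(0, n * L, 24L)
    grad[rows, ] <- P[rows, , drop = FALSE]
    grad[cbind(rows, cols)] <- grad[cbind(rows, cols)] - 1
    grad <- grad / count
  }
  list(loss = loss, grad = grad, count = count)
}

#' Train the regularized transformer autoencoder
#'
#' Seeded end-to-end training of encoder, decoder and classifier under
#' the weighted total loss (reconstruction + classification cross-entropy
#' + margin). The data are split into stratified train/validation sets;
#' with stratified batching every mini-batch contains both classes, which
#' the margin loss requires.
#'
#' @param sequences An [Biostrings::AAStringSet] or named character
#'   vector of amino-acid sequences.
#' @param labels Class labels aligned with `sequences`: `"cas"`/
#'   `"noncas"`, or integers 1/0.
#' @param config A [casModelConfig()].
#' @param control A [trainingConfig()].
#' @return A trained [CasModel-class] whose history has one row per
#'   epoch (losses on both splits, accuracies, latent silhouettes) and
#'   which stores the eval-mode latents of the training split for the
#'   generative loop.
#' @export
trainCasModel <- function(sequences, labels, config = casModelConfig(),
                          control = trainingConfig()) {
  seqs <- .asSequenceCharacter(sequences)
  labels <- .normalizeLabels(labels, length(seqs))
  tc <- control
  if (tc$loss$gamma > 0 && length(unique(labels)) < 2L)
    stop("margin loss (gamma > 0) requires both classes in the dataset")
  tokens <- encodeSequences(seqs, config$maxLen)
  model <- initCasModel(config)          # seeds weights from config$rngSeed
  params <- model@params
  set.seed(tc$rngSeed)
  # stratified train/validation split
  n <- length(seqs)
  valIdx <- integer(0)
  if (tc$valFraction > 0) {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      nv <- floor(length(idx) * tc$valFraction)
      if (nv > 0L) valIdx <- c(valIdx, sample(idx, nv))
    }
  }
  trIdx <- setdiff(seq_len(n), valIdx)
  trTok <- tokens[trIdx, , drop = FALSE]; trLab <- labels[trIdx]
  vaTok <- tokens[valIdx, , drop = FALSE]; vaLab <- labels[valIdx]
  cw <- if (tc$classWeighting)
    classWeightsFromCounts(c(sum(trLab == 1L), sum(trLab == 0L))) else NULL
  adam <- list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
  hist <- vector("list", tc$epochs)
  bestVal <- Inf; stall <- 0L
  for (epoch in seq_len(tc$epochs)) {
    batches <- .makeBatches(trLab, tc$batchSize,
                            tc$stratifiedBatching && tc$loss$gamma > 0)
    for (b in batches) {
      bt <- trTok[b, , drop = FALSE]; bl <- trLab[b]
      enc <- .encForward(params, model@posenc, config, bt, training = TRUE)
      dec <- .decForward(params, config, enc$latent)
      cls <- .clsForward(params, enc$latent)
      # reconstruction head
      rec <- .reconWithGrad(bt, dec$logits, wantGrad = TRUE)
      dLogTok <- rec$grad
      if (is.null(dLogTok)) dLogTok <- matrix(0, nrow(dec$logits), 24L)
      decB <- .decBackward(params, config, dec$cache,
                           tc$loss$alpha * dLogTok)
      # classification head (weighted CE gradient)
      P <- .softmaxRows(cls$logits)
      Y <- cbind(as.numeric(bl == 1L), as.numeric(bl == 0L))
      w <- if (is.null(cw)) rep(1, length(bl))
           else ifelse(bl == 1L, cw[[1L]], cw[[2L]])
      dCls <- tc$loss$beta * (P - Y) * (w / sum(w))
      clsB <- .clsBackward(params, enc$latent, cls$cache, dCls)
      # latent gradient: decoder + classifier (+ margin)
      dLat <- decB$dLatent + clsB$dLatent
      if (tc$loss$gamma > 0 && length(unique(bl)) == 2L)
        dLat <- dLat + tc$loss$gamma * .marginLossGrad(enc$latent, bl,
                                                       tc$margin)
      encB <- .encBackward(params, model@posenc, config, enc$cache, dLat)
      grads <- list(emb = encB$emb, layers = encB$layers,
                    Wlat = encB$Wlat, blat = encB$blat,
                    dec = decB$grads, cls = clsB$grads)
      gn <- sqrt(.gradSqNorm(grads))
      if (is.finite(gn) && gn > tc$gradientClipNorm)
        grads <- .scaleGrads(grads, tc$gradientClipNorm / gn)
      step <- .adamStep(params, grads, adam, tc$learningRate)
      params <- step$params; adam <- step$state
    }
    trEval <- .evalSplit(params, model@posenc, config, trTok, trLab, tc, cw)
    vaEval <- if (length(valIdx) > 0L)
      .evalSplit(params, model@posenc, config, vaTok, vaLab, tc, cw)
    else trEval
    silTr <- .safeSilhouette(trEval$latents, trLab)
    silVa <- if (length(valIdx) > 0L) .safeSilhouette(vaEval$latents, vaLab)
             else silTr
    hist[[epoch]] <- data.frame(
      epoch = epoch,
      trainRecon = trEval$breakdown[["recon"]],
      trainCE = trEval$breakdown[["classification"]],
      trainMargin = trEval$breakdown[["margin"]],
      trainTotal = trEval$breakdown[["total"]],
      valRecon = vaEval$breakdown[["recon"]],
      valCE = vaEval$breakdown[["classification"]],
      valMargin = vaEval$breakdown[["margin"]],
      valTotal = vaEval$breakdown[["total"]],
      trainAccuracy = trEval$accuracy,
      valAccuracy = vaEval$accuracy,
      trainSilhouette = silTr,
      valSilhouette = silVa)
    if (tc$verbose)
      message(sprintf(
        "epoch %d: train total %.4f, val total %.4f, val acc %.3f, sil %.3f",
        epoch, hist[[epoch]]$trainTotal, hist[[epoch]]$valTotal,
        hist[[epoch]]$valAccuracy, silVa))
    if (tc$earlyStopping) {
      if (hist[[epoch]]$valTotal < bestVal - 1e-8) {
        bestVal <- hist[[epoch]]$valTotal; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= tc$patience) break
    }
  }
  model@params <- params
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model@trainLatents <- .evalSplit(params, model@posenc, config, trTok,
                                   trLab, tc, cw)$latents
  model@trainLabels <- trLab
  model@trained <- TRUE
  methods::validObject(model)
  model
}

.safeSilhouette <- function(latents, labels) {
  if (length(unique(labels)) < 2L || length(labels) < 3L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(labels) + 1L, stats::dist(latents))
  mean(sil[, "sil_width"])
}

#' Latent-space separation diagnostics
#'
#' Quantifies how well Cas and non-Cas latents separate: the mean
#' silhouette width (Euclidean distance) plus the intra-class and
#' inter-class mean squared pairwise distances used by the margin loss.
#'
#' @param latents Matrix with one latent per row.
#' @param labels Integer vector (1 = Cas, 0 = non-Cas) or
#'   `"cas"`/`"noncas"`.
#' @return A list with elements `silhouette` (in `[-1, 1]`), `dCas`,
#'   `dNonCas`, `dInter`.
#' @export
evaluateLatentSeparation <- function(latents, labels) {
  latents <- .asLatentMatrix(latents)
  labels <- .normalizeLabels(labels, nrow(latents))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  if (min(table(labels)) < 2L)
    stop("at least 2 samples per class required")
  cas <- latents[labels == 1L, , drop = FALSE]
  non <- latents[labels == 0L, , drop = FALSE]
  list(silhouette = .safeSilhouette(latents, labels),
       dCas = intraClassDistance(cas),
       dNonCas = intraClassDistance(non),
       dInter = interClassDistance(cas, non))
}

#' Save and restore a trained model
#'
#' A checkpoint is a single serialized file holding the configuration,
#' the weights, the training history and the stored training latents.
#'
#' @param model A `CasModel`.
#' @param path Checkpoint file path.
#' @return `saveCasModel` returns `path` invisibly; `readCasModel`
#'   returns the restored `CasModel`.
#' @export
saveCasModel <- function(model, path) {
  stopifnot(methods::is(model, "CasModel"))
  saveRDS(list(config = model@config, params = model@params,
               history = model@history, trainLatents = model@trainLatents,
               trainLabels = model@trainLabels, trained = model@trained),
          path)
  invisible(path)
}

#' @rdname saveCasModel
#' @export
readCasModel <- function(path) {
  x <- readRDS(path)
  methods::new("CasModel", config = x$config, params = x$params,
               posenc = .positionalEncoding(x$config$maxLen,
                                            x$config$modelWidth),
               history = x$history, trainLatents = x$trainLatents,
               trainLabels = x$trainLabels, trained = x$trained)
}
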