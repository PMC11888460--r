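# Shared fixtures and independent reference implementations. The brute
# force oracles below are naive double loops written directly from the
# definitions; they deliberately share no code with the package internals
# they check.

tinyModelConfig <- function(seed = 5L, maxLen = 32L) {
  casModelConfig(latentDim = 8L, encoderLayers = 1L, attentionHeads = 2L,
                 modelWidth = 16L, feedforwardWidth = 32L, dropoutRate = 0,
                 maxLen = maxLen, decoderConvLayers = 2L,
                 decoderChannels = 8L, rngSeed = seed)
}

randomProteins <- function(n, minLen = 3L, maxLen = 12L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(minLen:maxLen, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# mean over unordered pairs of squared Euclidean distance, naive loops
bfIntra <- function(X) {
  m <- nrow(X)
  if (is.null(m) || m < 2L) return(0)
  tot <- 0; cnt <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    tot <- tot + sum((X[i, ] - X[j, ])^2)
    cnt <- cnt + 1
  }
  tot / cnt
}

bfInter <- function(A, B) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + sum((A[i, ] - B[j, ])^2)
  tot / (nrow(A) * nrow(B))
}

bfMargin <- function(X, labels, wCas = 1, wNonCas = 1, wInter = 1) {
  A <- X[labels == 1L, , drop = FALSE]
  B <- X[labels == 0L, , drop = FALSE]
  inter <- if (nrow(A) > 0L && nrow(B) > 0L) bfInter(A, B) else 0
  wCas * bfIntra(A) + wNonCas * bfIntra(B) - wInter * inter
}

# a small trained model on a 60-sequence two-family dataset, cached so the
# generation tests pay the training cost once per session
.fixtures <- new.env(parent = emptyenv())

smallTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    data <- syntheticBenchmark(rngSeed = 3L, nPerClass = 30L,
                               consensusLength = 40L)
    cfg <- casModelConfig(latentDim = 8L, encoderLayers = 1L,
                          attentionHeads = 2L, modelWidth = 24L,
                          feedforwardWidth = 48L, dropoutRate = 0.1,
                          maxLen = 44L, decoderConvLayers = 2L,
                          decoderChannels = 16L, rngSeed = 21L)
    ctl <- trainingConfig(epochs = 20L, batchSize = 20L, rngSeed = 31L)
    .fixtures$model <- trainCasModel(data$sequences, data$labels$class,
                                     cfg, ctl)
    .fixtures$data <- data
  }
  list(model = .fixtures$model, data = .fixtures$data)
}
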