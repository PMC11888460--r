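test_that("encoder produces one latent per sequence, deterministically in eval mode", {
  cfg <- tinyModelConfig()
  m <- initCasModel(cfg)
  tok <- encodeSequences(c("ACDEF", "MKVLAWY"), maxLen = cfg$maxLen)
  lat <- encodeToLatent(m, tok)
  expect_identical(dim(lat), c(2L, cfg$latentDim))
  expect_true(all(is.finite(lat)))
  expect_identical(lat, encodeToLatent(m, tok))
  expect_error(encodeToLatent(m, matrix(99L, 1L, cfg$maxLen)), "0..23")
})

test_that("latents are invariant to extra right padding (masked pooling)", {
  cfg <- tinyModelConfig(maxLen = 40L)
  m <- initCasModel(cfg)
  s <- "MKVLAACDEFGH"
  latShort <- encodeToLatent(m, encodeSequences(s, maxLen = 20L))
  latLong <- encodeToLatent(m, encodeSequences(s, maxLen = 40L))
  expect_equal(latShort, latLong, tolerance = 1e-12)
})

test_that("two models built from the same config are identical maps", {
  cfg <- tinyModelConfig(seed = 11L)
  tok <- encodeSequences(c("WYACD", "PQRST"), maxLen = cfg$maxLen)
  m1 <- initCasModel(cfg); m2 <- initCasModel(cfg)
  expect_identical(encodeToLatent(m1, tok), encodeToLatent(m2, tok))
  lat <- encodeToLatent(m1, tok)
  expect_identical(decodeFromLatent(m1, lat[1L, ]),
                   decodeFromLatent(m2, lat[1L, ]))
})

test_that("decoder logits have shape maxLen x 24 and decode to sequences", {
  cfg <- tinyModelConfig()
  m <- initCasModel(cfg)
  lat <- rnorm(cfg$latentDim)
  logits <- decodeFromLatent(m, lat)
  expect_identical(dim(logits), c(cfg$maxLen, 24L))
  expect_identical(logits, decodeFromLatent(m, lat))   # eval determinism
  codes <- max.col(logits, ties.method = "first") - 1L
  expect_identical(decodeLatentToSequence(m, lat),
                   suppressWarnings(decodeTokens(codes)))
  expect_error(decodeFromLatent(m, c(NA, rnorm(cfg$latentDim - 1L))),
               "finite")
  expect_error(decodeFromLatent(m, rnorm(3L)), "latentDim")
})

test_that("classifier outputs normalized probability pairs", {
  cfg <- tinyModelConfig()
  m <- initCasModel(cfg)
  set.seed(1)
  lat <- matrix(rnorm(6 * cfg$latentDim), 6L)
  p <- classifyLatent(m, lat)
  expect_identical(colnames(p), c("cas", "noncas"))
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 6L), tolerance = 1e-6)
  expect_error(classifyLatent(m, c(Inf, rnorm(cfg$latentDim - 1L))),
               "finite")
})

test_that("softmax matches analytic values", {
  sm <- casdesign:::.softmaxRows
  expect_equal(as.vector(sm(matrix(c(0, 0), 1L))), c(0.5, 0.5))
  expect_equal(as.vector(sm(matrix(c(log(3), 0), 1L))), c(0.75, 0.25))
  set.seed(2)
  Z <- matrix(rnorm(40, sd = 5), 8L)
  expect_equal(rowSums(sm(Z)), rep(1, 8L), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("casdesign")
  cfg <- casModelConfig(latentDim = 4L, encoderLayers = 1L,
                        attentionHeads = 2L, modelWidth = 6L,
                        feedforwardWidth = 8L, dropoutRate = 0,
                        maxLen = 8L, decoderConvLayers = 1L,
                        decoderChannels = 4L, rngSeed = 17L)
  m <- initCasModel(cfg)
  tok <- encodeSequences(c("ACDEF", "MKV", "WYA"), maxLen = cfg$maxLen)
  labels <- c(1L, 0L, 1L)
  lossFn <- function(params) {
    enc <- ns$.encForward(params, m@posenc, cfg, tok)
    dec <- ns$.decForward(params, cfg, enc$latent)
    cls <- ns$.clsForward(params, enc$latent)
    rec <- ns$.reconWithGrad(tok, dec$logits)
    ce <- classificationLoss(ns$.softmaxRows(cls$logits), labels)
    rec$loss + ce + marginLoss(enc$latent, labels)
  }
  params <- m@params
  enc <- ns$.encForward(params, m@posenc, cfg, tok)
  dec <- ns$.decForward(params, cfg, enc$latent)
  cls <- ns$.clsForward(params, enc$latent)
  rec <- ns$.reconWithGrad(tok, dec$logits, wantGrad = TRUE)
  decB <- ns$.decBackward(params, cfg, dec$cache, rec$grad)
  P <- ns$.softmaxRows(cls$logits)
  Y <- cbind(as.numeric(labels == 1L), as.numeric(labels == 0L))
  clsB <- ns$.clsBackward(params, enc$latent, cls$cache,
                          (P - Y) / length(labels))
  dLat <- decB$dLatent + clsB$dLatent +
    ns$.marginLossGrad(enc$latent, labels)
  encB <- ns$.encBackward(params, m@posenc, cfg, enc$cache, dLat)
  grads <- list(emb = encB$emb, layers = encB$layers, Wlat = encB$Wlat,
                blat = encB$blat, dec = decB$grads, cls = clsB$grads)
  # probe a few coordinates in structurally distinct parameter groups
  probes <- list(
    list(g = grads$emb, set = function(p, v) { p$emb <- v; p },
         get = function(p) p$emb),
    list(g = grads$layers[[1L]]$Wq,
         set = function(p, v) { p$layers[[1L]]$Wq <- v; p },
         get = function(p) p$layers[[1L]]$Wq),
    list(g = grads$layers[[1L]]$ln2g,
         set = function(p, v) { p$layers[[1L]]$ln2g <- v; p },
         get = function(p) p$layers[[1L]]$ln2g),
    list(g = grads$Wlat, set = function(p, v) { p$Wlat <- v; p },
         get = function(p) p$Wlat),
    list(g = grads$dec$convs[[1L]]$W,
         set = function(p, v) { p$dec$convs[[1L]]$W <- v; p },
         get = function(p) p$dec$convs[[1L]]$W),
    list(g = grads$cls$W2, set = function(p, v) { p$cls$W2 <- v; p },
         get = function(p) p$cls$W2))
  eps <- 1e-5
  set.seed(9)
  for (pr in probes) {
    leaf <- pr$get(params)
    for (j in sample(length(leaf), 3L)) {
      up <- leaf; up[j] <- up[j] + eps
      dn <- leaf; dn[j] <- dn[j] - eps
      num <- (lossFn(pr$set(params, up)) - lossFn(pr$set(params, dn))) /
        (2 * eps)
      expect_equal(as.vector(pr$g)[j], num, tolerance = 1e-4)
    }
  }
})

test_that("the autoencoder can memorize a 5-sequence toy set exactly", {
  seqs <- c(s1 = "MKVLAADEFGHWWKLIRT", s2 = "ACDEFGHIKLMNPQRSTVWY",
            s3 = "GGGHHHIIIKKKLLL", s4 = "WYWYWYACACDEDE",
            s5 = "PQRSTPQRSTPQRST")
  labels <- c(1L, 1L, 1L, 0L, 0L)
  cfg <- casModelConfig(latentDim = 8L, encoderLayers = 1L,
                        attentionHeads = 2L, modelWidth = 32L,
                        feedforwardWidth = 64L, dropoutRate = 0,
                        maxLen = 32L, decoderConvLayers = 2L,
                        decoderChannels = 32L, rngSeed = 5L)
  ctl <- trainingConfig(epochs = 300L, batchSize = 5L,
                        learningRate = 3e-3, valFraction = 0,
                        loss = lossWeights(1, 1, 0), rngSeed = 11L)
  m <- trainCasModel(seqs, labels, cfg, ctl)
  h <- trainingHistory(m)
  expect_lt(h$trainTotal[nrow(h)], 0.01)
  lat <- encodeToLatent(m, encodeSequences(seqs, cfg$maxLen))
  expect_identical(decodeLatentToSequence(m, lat), unname(seqs))
})
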