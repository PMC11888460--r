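test_that("the classification gate routes latents by Cas probability", {
  fx <- smallTrainedModel()
  tl <- trainingLatents(fx$model)
  casLat <- tl$latents[tl$labels == 1L, , drop = FALSE][1L, ]
  nonLat <- tl$latents[tl$labels == 0L, , drop = FALSE][1L, ]
  gCas <- classificationGate(fx$model, casLat, 0.5)
  gNon <- classificationGate(fx$model, nonLat, 0.5)
  expect_true(gCas$pass)
  expect_false(gNon$pass)
  expect_equal(gCas$casProbability,
               unname(classifyLatent(fx$model, casLat)[1L, "cas"]))
  # a zero threshold lets every finite latent through
  expect_true(classificationGate(fx$model, nonLat, 0)$pass)
})

test_that("the mock structure oracle is deterministic and peaked at its target", {
  fx <- smallTrainedModel()
  maxLen <- modelConfig(fx$model)$maxLen
  casSeq <- as.character(fx$data$sequences[fx$data$labels$class == "cas"][[2L]])
  far <- as.character(fx$data$sequences[fx$data$labels$class == "noncas"][[1L]])
  target <- as.vector(encodeToLatent(fx$model,
                                     encodeSequences(casSeq, maxLen)))
  oracle <- mockStructureOracle(fx$model, target)
  expect_identical(oracle(casSeq), oracle(casSeq))
  # the sequence that encodes onto the target attains the maximal score 1
  expect_equal(oracle(casSeq), 1, tolerance = 1e-9)
  expect_gt(oracle(casSeq), oracle(far))
  expect_true(oracle(far) >= 0 && oracle(far) <= 1)
})

genFixture <- function(budget = 18L, seed = 4L, method = "bo") {
  fx <- smallTrainedModel()
  tl <- trainingLatents(fx$model)
  target <- tl$latents[tl$labels == 1L, , drop = FALSE][2L, ]
  oracle <- mockStructureOracle(fx$model, target)
  refDb <- fx$data$sequences[fx$data$labels$class == "cas"]
  cfg <- generationConfig(iterationBudget = budget, initialSeedCount = 5L,
                          rngSeed = seed)
  list(cands = generateCandidates(fx$model, oracle, refDb, cfg,
                                  method = method),
       model = fx$model, oracle = oracle, refDb = refDb, cfg = cfg)
}

test_that("generation produces a complete, sound candidate ledger", {
  g <- genFixture()
  cands <- g$cands
  expect_equal(nrow(cands), 18L)
  expect_true(all(cands$status %in%
                    c("gated_out", "scored_failed", "accepted",
                      "rejected_similar")))
  # gate soundness: a structure score implies the gate was passed
  scored <- !is.na(cands$structureScore)
  expect_true(all(cands$casProbability[scored] >= g$cfg$gateThreshold))
  expect_true(all(is.na(cands$structureScore[cands$status == "gated_out"])))
  # accepted candidates pass both the gate and the novelty filter
  acc <- cands[cands$status == "accepted", ]
  expect_true(all(acc$casProbability >= g$cfg$gateThreshold))
  expect_true(all(acc$maxIdentityPercent <
                    g$cfg$identityThresholdPercent))
  # best-so-far objective trace is non-decreasing
  trace <- S4Vectors::metadata(cands)$bestTrace
  expect_true(all(diff(trace) >= 0))
})

test_that("stored identities match brute-force recomputation", {
  g <- genFixture(budget = 10L)
  cands <- g$cands
  withSeq <- which(!is.na(cands$sequence) & nchar(cands$sequence) > 0L)
  db <- as.character(g$refDb)
  for (i in withSeq) {
    bf <- max(vapply(db, function(s)
      pairwiseIdentity(cands$sequence[i], s), numeric(1)))
    expect_equal(cands$maxIdentityPercent[i], bf, tolerance = 1e-6)
  }
})

test_that("a budget equal to the seed count yields exactly the seeds", {
  g <- genFixture(budget = 5L)
  expect_equal(nrow(g$cands), 5L)
  expect_equal(g$cands$iteration, 1:5)
})

test_that("generation is reproducible and writes a readable ledger", {
  g1 <- genFixture(budget = 12L, seed = 9L)
  g2 <- genFixture(budget = 12L, seed = 9L)
  expect_identical(as.data.frame(g1$cands[, setdiff(colnames(g1$cands),
                                                    "latent")]),
                   as.data.frame(g2$cands[, setdiff(colnames(g2$cands),
                                                    "latent")]))
  expect_identical(g1$cands$latent, g2$cands$latent)
  dir <- withr::local_tempdir()
  writeCandidates(g1$cands, dir)
  tab <- read.delim(file.path(dir, "candidates.tsv"))
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("id", "status", "casProbability") %in% names(tab)))
})

test_that("Bayesian proposals outperform random search toward the planted target", {
  fx <- smallTrainedModel()
  tl <- trainingLatents(fx$model)
  target <- tl$latents[tl$labels == 1L, , drop = FALSE][2L, ]
  oracle <- mockStructureOracle(fx$model, target)
  refDb <- fx$data$sequences[fx$data$labels$class == "cas"]
  wins <- 0L
  nSeeds <- 6L
  for (s in seq_len(nSeeds)) {
    cfg <- generationConfig(iterationBudget = 25L, rngSeed = s)
    bo <- generateCandidates(fx$model, oracle, refDb, cfg, method = "bo")
    rnd <- generateCandidates(fx$model, oracle, refDb, cfg,
                              method = "random")
    if (max(bo$objective) >= max(rnd$objective)) wins <- wins + 1L
  }
  expect_gte(wins, nSeeds - 1L)
})
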