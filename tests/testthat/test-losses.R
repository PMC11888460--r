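test_that("classification cross-entropy matches analytic values", {
  perfect <- matrix(c(1, 0), 1L)
  expect_equal(classificationLoss(perfect, 1L), 0)
  uniform <- matrix(c(0.5, 0.5), 1L)
  expect_equal(classificationLoss(uniform, 1L), 0.693147, tolerance = 1e-6)
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(classificationLoss(two, c(1L, 1L)), 1.039721,
               tolerance = 1e-6)
  expect_warning(v <- classificationLoss(matrix(c(0, 1), 1L), 1L),
                 "clamped")
  expect_true(is.finite(v) && v > 0)
})

test_that("class weighting is an inverse-frequency weighted mean", {
  w <- classWeightsFromCounts(c(3308, 597))
  expect_equal(unname(w), c(3905 / 6616, 3905 / 1194), tolerance = 1e-6)
  expect_equal(unname(classWeightsFromCounts(c(50, 50))), c(1, 1))
  expect_equal(classWeightsFromCounts(c(30, 70)),
               classWeightsFromCounts(c(300, 700)))
  expect_error(classWeightsFromCounts(c(0, 10)), ">= 1")
  # balanced weights reduce to the plain mean
  set.seed(4)
  p <- matrix(runif(10, 0.1, 0.9)); p <- cbind(p, 1 - p)
  lab <- rep(c(1L, 0L), 5L)
  expect_equal(classificationLoss(p, lab, c(1, 1)),
               classificationLoss(p, lab), tolerance = 1e-12)
})

test_that("latent distance terms match hand-worked examples", {
  expect_equal(intraClassDistance(rbind(c(1, 2), c(1, 2))), 0)
  expect_equal(intraClassDistance(rbind(c(0, 0), c(2, 0))), 4)
  expect_equal(intraClassDistance(rbind(c(0, 0), c(2, 0), c(0, 2))),
               16 / 3, tolerance = 1e-12)
  expect_equal(intraClassDistance(matrix(numeric(0), 0L, 2L)), 0)
  expect_equal(intraClassDistance(c(1, 2, 3)), 0)
  expect_equal(interClassDistance(c(0, 0), c(3, 4)), 25)
  expect_equal(interClassDistance(rbind(c(0, 0), c(2, 0)), c(3, 4)), 21)
  expect_error(interClassDistance(matrix(numeric(0), 0L, 2L), c(1, 2)),
               "nonempty")
  expect_error(interClassDistance(c(1, 2), c(1, 2, 3)), "dimensions")
})

test_that("margin loss composes its terms and is translation invariant", {
  X <- rbind(c(0, 0), c(2, 0), c(3, 4))
  lab <- c(1L, 1L, 0L)
  expect_equal(marginLoss(X, lab), 4 + 0 - 21)
  expect_equal(marginLoss(X, lab, marginWeights(0, 0, 0)), 0)
  shift <- sweep(X, 2L, c(-7.3, 2.1), "+")
  expect_equal(marginLoss(shift, lab), marginLoss(X, lab),
               tolerance = 1e-9)
  expect_warning(v <- marginLoss(X, c(1L, 1L, 1L)), "absent")
  expect_equal(v, intraClassDistance(X))
})

test_that("distance and margin computations agree with brute force", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(4:12, 1L); d <- sample(2:8, 1L)
    X <- matrix(rnorm(n * d), n)
    lab <- c(1L, 0L, sample(c(0L, 1L), n - 2L, replace = TRUE))
    w <- runif(3, 0.2, 2)
    expect_equal(intraClassDistance(X[lab == 1L, , drop = FALSE]),
                 bfIntra(X[lab == 1L, , drop = FALSE]), tolerance = 1e-9)
    expect_equal(interClassDistance(X[lab == 1L, , drop = FALSE],
                                    X[lab == 0L, , drop = FALSE]),
                 bfInter(X[lab == 1L, , drop = FALSE],
                         X[lab == 0L, , drop = FALSE]), tolerance = 1e-9)
    expect_equal(marginLoss(X, lab, marginWeights(w[1], w[2], w[3])),
                 bfMargin(X, lab, w[1], w[2], w[3]), tolerance = 1e-9)
    # permutation invariance and quadratic scaling
    perm <- sample(n)
    expect_equal(marginLoss(X[perm, ], lab[perm]), marginLoss(X, lab),
                 tolerance = 1e-9)
    s <- runif(1, 0.5, 3)
    expect_equal(intraClassDistance(s * X), s^2 * intraClassDistance(X),
                 tolerance = 1e-9)
  }
})

test_that("pulling class centers apart raises separation and lowers margin loss", {
  set.seed(55)
  base <- matrix(rnorm(40), 20L)
  lab <- rep(c(1L, 0L), each = 10L)
  vals <- sapply(c(0, 2, 5, 10), function(gap) {
    X <- base
    X[lab == 0L, 1L] <- X[lab == 0L, 1L] + gap
    c(inter = interClassDistance(X[lab == 1L, ], X[lab == 0L, ]),
      margin = marginLoss(X, lab))
  })
  expect_true(all(diff(vals["inter", ]) > 0))
  expect_true(all(diff(vals["margin", ]) < 0))
})

test_that("the hinge variant caps the separation term", {
  X <- rbind(c(0, 0), c(2, 0), c(3, 4))
  lab <- c(1L, 1L, 0L)                      # dCas = 4, dInter = 21
  # far apart relative to the cap: the inter term is flat at 0
  expect_equal(marginLoss(X, lab, marginWeights(interCap = 10)), 4)
  # closer than the cap: the term pushes toward interCap separation
  expect_equal(marginLoss(X, lab, marginWeights(interCap = 30)),
               4 + (30 - 21))
  # hinged loss is bounded below; the plain variant is not
  expect_gte(marginLoss(10 * X, lab, marginWeights(interCap = 10)), 0)
  expect_lt(marginLoss(10 * X, lab), -1000)
  # gradients in both hinge regimes match finite differences
  grad <- casdesign:::.marginLossGrad
  eps <- 1e-6
  for (cap in c(10, 30)) {
    w <- marginWeights(interCap = cap)
    G <- grad(X, lab, w)
    for (probe in list(c(1L, 1L), c(3L, 2L))) {
      up <- X; up[probe[1L], probe[2L]] <- up[probe[1L], probe[2L]] + eps
      dn <- X; dn[probe[1L], probe[2L]] <- dn[probe[1L], probe[2L]] - eps
      num <- (marginLoss(up, lab, w) - marginLoss(dn, lab, w)) / (2 * eps)
      expect_equal(G[probe[1L], probe[2L]], num, tolerance = 1e-6)
    }
  }
})

test_that("margin-loss gradient matches finite differences", {
  grad <- casdesign:::.marginLossGrad
  set.seed(77)
  X <- matrix(rnorm(14), 7L)
  lab <- c(1L, 1L, 1L, 0L, 0L, 1L, 0L)
  w <- marginWeights(1.3, 0.7, 1.1)
  G <- grad(X, lab, w)
  eps <- 1e-6
  for (probe in list(c(1L, 1L), c(4L, 2L), c(6L, 1L), c(7L, 2L))) {
    up <- X; up[probe[1L], probe[2L]] <- up[probe[1L], probe[2L]] + eps
    dn <- X; dn[probe[1L], probe[2L]] <- dn[probe[1L], probe[2L]] - eps
    num <- (marginLoss(up, lab, w) - marginLoss(dn, lab, w)) / (2 * eps)
    expect_equal(G[probe[1L], probe[2L]], num, tolerance = 1e-6)
  }
})

test_that("reconstruction loss matches analytic values and masks padding", {
  tgt <- encodeSequences("AC", maxLen = 6L)     # 1 3 4 2 0 0
  onehot <- matrix(-50, 6L, 24L)
  for (i in 1:6) onehot[i, tgt[1L, i] + 1L] <- 50
  expect_equal(reconstructionLoss(tgt, onehot), 0, tolerance = 1e-10)
  uniform <- matrix(0, 6L, 24L)
  expect_equal(reconstructionLoss(tgt, uniform), log(24),
               tolerance = 1e-9)
  expect_equal(reconstructionLoss(tgt, uniform, maskPadding = FALSE),
               log(24), tolerance = 1e-9)
  # N=1, T=2, true-token probabilities 0.5 and 0.25
  tgt2 <- matrix(c(3L, 4L), 1L)
  q1 <- rep(0.5 / 23, 24L); q1[4L] <- 0.5
  q2 <- rep(0.75 / 23, 24L); q2[5L] <- 0.25
  expect_equal(reconstructionLoss(tgt2, rbind(log(q1), log(q2)),
                                  maskPadding = FALSE),
               1.039721, tolerance = 1e-6)
})

test_that("masking excludes positions after the end token", {
  tgt <- encodeSequences("AC", maxLen = 6L)
  logits <- matrix(-50, 6L, 24L)
  for (i in 1:4) logits[i, tgt[1L, i] + 1L] <- 50   # perfect through <end>
  logits[5:6, 4L] <- 50                              # wrong at pad positions
  expect_equal(reconstructionLoss(tgt, logits), 0, tolerance = 1e-10)
  expect_gt(reconstructionLoss(tgt, logits, maskPadding = FALSE), 1)
})

test_that("total loss is the weighted sum and linear in each weight", {
  b <- totalLoss(1, 2, -3, lossWeights(1, 1, 1))
  expect_equal(unname(b["total"]), 0)
  expect_equal(unname(totalLoss(5, 7, 11, lossWeights(0, 0, 0))["total"]), 0)
  for (g in c(0.5, 1, 2)) {
    expect_equal(unname(totalLoss(1, 2, -3, lossWeights(1, 1, g))["total"]),
                 1 + 2 - 3 * g)
  }
  expect_error(lossWeights(-1, 1, 1), "nonnegative")
  b2 <- totalLoss(0.3, 0.7, -0.2, lossWeights(2, 3, 4))
  expect_equal(unname(b2["total"]),
               2 * 0.3 + 3 * 0.7 + 4 * (-0.2), tolerance = 1e-12)
})
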