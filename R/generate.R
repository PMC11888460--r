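# The generative loop: Bayesian optimization over the latent space with a
# Cas/non-Cas classification gate, decoding to sequences, pluggable
# structure scoring, and novelty filtering against a reference database.

#' Generation configuration
#'
#' @param iterationBudget Total number of latent evaluations, including
#'   the initial seeds; must be at least `initialSeedCount`.
#' @param initialSeedCount Number of seed latents drawn from encoded
#'   training Cas sequences (default 5).
#' @param seedPerturbationScale Standard deviation of the zero-mean
#'   Gaussian perturbation added to each seed latent (default 0.25).
#' @param gateThreshold Classifier probability required to pass the Cas
#'   gate (default 0.5).
#' @param acquisition `"EI"` (expected improvement, default) or `"UCB"`.
#' @param ucbKappa UCB exploration weight (default 2).
#' @param identityThresholdPercent Novelty threshold: candidates at or
#'   above this percent identity to any reference protein are rejected
#'   (default 50).
#' @param poolSize Acquisition candidate-pool size (default 256).
#' @param rngSeed Seed for the whole loop (default 1).
#' @return A validated list of class `CasGenerationConfig`.
#' @export
generationConfig <- function(iterationBudget = 40L, initialSeedCount = 5L,
                             seedPerturbationScale = 0.25,
                             gateThreshold = 0.5,
                             acquisition = c("EI", "UCB"), ucbKappa = 2,
                             identityThresholdPercent = 50,
                             poolSize = 256L, rngSeed = 1L) {
  acquisition <- match.arg(acquisition)
  cfg <- list(iterationBudget = as.integer(iterationBudget),
              initialSeedCount = as.integer(initialSeedCount),
              seedPerturbationScale = seedPerturbationScale,
              gateThreshold = gateThreshold, acquisition = acquisition,
              ucbKappa = ucbKappa,
              identityThresholdPercent = identityThresholdPercent,
              poolSize = as.integer(poolSize),
              rngSeed = as.integer(rngSeed))
  stopifnot(cfg$initialSeedCount >= 1L,
            cfg$iterationBudget >= cfg$initialSeedCount,
            cfg$seedPerturbationScale >= 0,
            cfg$gateThreshold >= 0, cfg$gateThreshold < 1,
            cfg$ucbKappa > 0, cfg$poolSize >= 2L)
  class(cfg) <- "CasGenerationConfig"
  cfg
}

#' Classification gate
#'
#' Forwards a latent vector only if the classifier assigns it Cas
#' probability at or above the threshold; rejected vectors are returned
#' to the optimizer rather than decoded.
#'
#' @param model A trained `CasModel`.
#' @param latent A latent vector.
#' @param gateThreshold Probability threshold (default 0.5).
#' @return A list with `pass` (logical) and `casProbability`.
#' @export
classificationGate <- function(model, latent, gateThreshold = 0.5) {
  p <- classifyLatent(model, latent)[1L, "cas"]
  list(pass = unname(p) >= gateThreshold, casProbability = unname(p))
}

#' Deterministic mock structure oracle
#'
#' A stand-in for an external structure predictor, used for tests and
#' desk-scale runs: it scores a sequence by a radial basis around a
#' planted latent target, `exp(-||encode(seq) - target||^2 / tau)`, so
#' scores lie in `(0, 1]` with the maximum at sequences that encode onto
#' the target. Deterministic for a given sequence and model.
#'
#' @param model A trained `CasModel` (used to encode candidate
#'   sequences).
#' @param targetLatent The planted target latent vector.
#' @param tau Radial bandwidth. Default: the mean squared distance from
#'   the model's stored training latents (both classes) to the target, so
#'   scores spread over `(0, 1)` across the region the optimizer
#'   explores rather than collapsing to 0 away from the target.
#' @return A function `sequence -> score in [0, 1]`.
#' @export
mockStructureOracle <- function(model, targetLatent, tau = NULL) {
  stopifnot(methods::is(model, "CasModel"))
  targetLatent <- as.numeric(targetLatent)
  if (is.null(tau)) {
    lat <- model@trainLatents
    if (nrow(lat) > 0L)
      tau <- mean(rowSums(sweep(lat, 2L, targetLatent)^2))
    if (is.null(tau) || !is.finite(tau) || tau <= 0)
      tau <- length(targetLatent)
  }
  maxLen <- model@config$maxLen
  force(model)
  function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              nchar(sequence) > 0L)
    lat <- encodeToLatent(model, encodeSequences(sequence, maxLen))
    exp(-sum((as.numeric(lat) - targetLatent)^2) / tau)
  }
}

# evaluate one latent point: gate -> decode -> oracle; the BO objective is
# the structure score for gated-pass points and (casProbability - 1) for
# gated-out points, keeping all gated-out values below all scored values
.evaluateLatent <- function(model, latent, oracle, gateThreshold) {
  gate <- classificationGate(model, latent, gateThreshold)
  if (!gate$pass)
    return(list(status = "gated_out", casProbability = gate$casProbability,
                sequence = NA_character_, structureScore = NA_real_,
                objective = gate$casProbability - 1))
  seq <- suppressWarnings(decodeLatentToSequence(model, latent))
  if (nchar(seq) == 0L)
    return(list(status = "scored_failed", casProbability = gate$casProbability,
                sequence = seq, structureScore = NA_real_, objective = 0))
  score <- tryCatch(oracle(seq), error = function(e) NA_real_)
  if (!is.finite(score))
    return(list(status = "scored_failed", casProbability = gate$casProbability,
                sequence = seq, structureScore = NA_real_, objective = 0))
  list(status = "scored", casProbability = gate$casProbability,
       sequence = seq, structureScore = score, objective = score)
}

#' Generate candidate Cas proteins
#'
#' Runs the full generative loop. Seed latents are encoded training Cas
#' sequences plus Gaussian perturbations; each subsequent iteration fits
#' a GP surrogate to all observed (latent, objective) pairs, proposes the
#' acquisition maximizer, gates it through the classifier, decodes it and
#' scores it with the structure oracle. Finally every scored candidate is
#' filtered for novelty against the reference database.
#'
#' @param model A trained `CasModel`.
#' @param oracle A structure oracle: a function mapping an amino-acid
#'   sequence to a score in `[0, 1]` (e.g. [mockStructureOracle()], or an
#'   adapter around an external predictor). Oracle failures mark the
#'   candidate `scored_failed` with objective 0 and the loop continues.
#' @param referenceDb Known proteins ([Biostrings::AAStringSet] or
#'   character vector) for the novelty filter.
#' @param config A [generationConfig()].
#' @param method `"bo"` (Bayesian optimization, default) or `"random"`
#'   (uniform proposals from the same inflated box; the paired baseline).
#' @return An [S4Vectors::DataFrame] with one row per evaluated latent:
#'   `id`, `iteration`, `status` (`gated_out`, `scored_failed`,
#'   `rejected_similar`, or `accepted`), `casProbability`, `sequence`,
#'   `structureScore`, `objective`, `maxIdentityPercent`, and a `latent`
#'   matrix column. `metadata(x)$bestTrace` holds the non-decreasing
#'   best-so-far objective per iteration.
#' @export
generateCandidates <- function(model, oracle, referenceDb,
                               config = generationConfig(),
                               method = c("bo", "random")) {
  method <- match.arg(method)
  stopifnot(methods::is(model, "CasModel"))
  if (!model@trained) stop("model must be trained")
  db <- .asSequenceCharacter(referenceDb)
  if (length(db) == 0L) stop("reference database is empty")
  casLat <- model@trainLatents[model@trainLabels == 1L, , drop = FALSE]
  if (nrow(casLat) == 0L) stop("model stores no Cas training latents")
  d <- ncol(casLat)
  set.seed(config$rngSeed)
  k <- config$initialSeedCount
  pick <- sample.int(nrow(casLat), k, replace = k > nrow(casLat))
  seeds <- casLat[pick, , drop = FALSE] +
    matrix(stats::rnorm(k * d, sd = config$seedPerturbationScale), k, d)
  budget <- config$iterationBudget
  latents <- matrix(NA_real_, budget, d)
  evals <- vector("list", budget)
  for (i in seq_len(k)) {
    latents[i, ] <- seeds[i, ]
    evals[[i]] <- .evaluateLatent(model, seeds[i, ], oracle,
                                  config$gateThreshold)
  }
  i <- k
  while (i < budget) {
    i <- i + 1L
    obs <- latents[seq_len(i - 1L), , drop = FALSE]
    if (method == "bo") {
      fit <- tryCatch(gpFit(obs, vapply(evals[seq_len(i - 1L)], `[[`,
                                        numeric(1), "objective")),
                      error = function(e) NULL)
      x <- proposeNextLatent(fit, acquisition = config$acquisition,
                             ucbKappa = config$ucbKappa,
                             poolSize = config$poolSize, fallbackX = obs)
    } else {
      x <- as.vector(.uniformInBox(1L, .observedBox(obs)))
    }
    latents[i, ] <- x
    evals[[i]] <- .evaluateLatent(model, x, oracle, config$gateThreshold)
  }
  out <- S4Vectors::DataFrame(
    id = sprintf("cand%03d", seq_len(budget)),
    iteration = seq_len(budget),
    status = vapply(evals, `[[`, character(1), "status"),
    casProbability = vapply(evals, `[[`, numeric(1), "casProbability"),
    sequence = vapply(evals, `[[`, character(1), "sequence"),
    structureScore = vapply(evals, `[[`, numeric(1), "structureScore"),
    objective = vapply(evals, `[[`, numeric(1), "objective"),
    maxIdentityPercent = NA_real_)
  out$latent <- latents
  out <- noveltyFilter(out, db, config$identityThresholdPercent)
  S4Vectors::metadata(out) <- list(bestTrace = cummax(out$objective),
                                   method = method, config = config)
  out
}

#' Accepted designs as an AAStringSet
#'
#' @param candidates A candidate ledger from [generateCandidates()].
#' @return An [Biostrings::AAStringSet] of the accepted sequences, named
#'   by candidate id.
#' @export
acceptedSequences <- function(candidates) {
  keep <- which(candidates$status == "accepted")
  out <- Biostrings::AAStringSet(candidates$sequence[keep])
  names(out) <- candidates$id[keep]
  out
}

#' Write a candidate ledger and accepted designs to disk
#'
#' Writes `candidates.tsv` (id, iteration, status, casProbability,
#' structureScore, maxIdentityPercent, sequence) and `accepted.fasta`
#' into `dir`.
#'
#' @param candidates A candidate ledger from [generateCandidates()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCandidates <- function(candidates, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as.data.frame(candidates[, c("id", "iteration", "status",
                                      "casProbability", "structureScore",
                                      "maxIdentityPercent", "sequence")])
  utils::write.table(tab, file.path(dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  acc <- acceptedSequences(candidates)
  if (length(acc) > 0L) saveFasta(acc, file.path(dir, "accepted.fasta"))
  invisible(dir)
}
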