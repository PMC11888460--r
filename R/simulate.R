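# Seeded simulator of labeled protein families: a random consensus per
# family with independent per-site substitution, optionally lower rates
# inside conserved blocks (emulating the conserved nuclease-domain motifs
# that define real Cas families). Makes the whole pipeline trainable and
# testable without downloading a corpus.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of one synthetic protein family
#'
#' @param name Family name; record ids are `name_1`, `name_2`, ...
#' @param consensusLength Length of the family consensus.
#' @param nSequences Number of sequences to draw.
#' @param substitutionRate Per-site substitution probability `mu` in
#'   `[0, 1]` outside conserved blocks.
#' @param conservedBlocks Optional `data.frame` with columns `start`,
#'   `end` (1-based, inclusive, within the consensus) and `rate`
#'   (site-wise substitution rate inside the block, at most `mu`).
#' @param classLabel `"cas"` or `"noncas"`.
#' @param naturalFrequencies Draw the consensus from Robinson-Robinson
#'   amino-acid frequencies instead of uniformly (default `FALSE`;
#'   uniform consensi maximize between-family divergence, which keeps
#'   fixtures crisp).
#' @param rngSeed Seed for this family.
#' @return A validated list of class `CasFamilySpec`.
#' @export
familySpec <- function(name, consensusLength, nSequences,
                       substitutionRate = 0.1, conservedBlocks = NULL,
                       classLabel = c("cas", "noncas"),
                       naturalFrequencies = FALSE, rngSeed = 1L) {
  classLabel <- match.arg(classLabel)
  spec <- list(name = as.character(name),
               consensusLength = as.integer(consensusLength),
               nSequences = as.integer(nSequences),
               substitutionRate = substitutionRate,
               conservedBlocks = conservedBlocks,
               classLabel = classLabel,
               naturalFrequencies = isTRUE(naturalFrequencies),
               rngSeed = as.integer(rngSeed))
  stopifnot(spec$consensusLength >= 1L, spec$nSequences >= 1L,
            spec$substitutionRate >= 0, spec$substitutionRate <= 1)
  if (!is.null(conservedBlocks)) {
    stopifnot(is.data.frame(conservedBlocks),
              all(c("start", "end", "rate") %in% names(conservedBlocks)))
    with(conservedBlocks, stopifnot(
      all(start >= 1L), all(end <= spec$consensusLength),
      all(start <= end), all(rate >= 0),
      all(rate <= spec$substitutionRate)))
  }
  class(spec) <- "CasFamilySpec"
  spec
}

# Robinson & Robinson (1991) background amino-acid frequencies, order .AA20
.AA_FREQ <- c(0.0780, 0.0192, 0.0535, 0.0629, 0.0405, 0.0738, 0.0219,
              0.0514, 0.0595, 0.0901, 0.0224, 0.0448, 0.0520, 0.0426,
              0.0512, 0.0712, 0.0584, 0.0644, 0.0132, 0.0341)

#' Draw one synthetic protein family
#'
#' Draws a random consensus, then `nSequences` copies with independent
#' per-site substitution at each site's applicable rate (substitutions
#' are uniform over the 19 other residues). Seeded and reproducible.
#'
#' @param spec A [familySpec()].
#' @return An [Biostrings::AAStringSet] named `name_i`, with the label in
#'   `metadata(x)$classLabel` and the consensus in
#'   `metadata(x)$consensus`.
#' @export
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "CasFamilySpec"))
  set.seed(spec$rngSeed)
  L <- spec$consensusLength
  prob <- if (spec$naturalFrequencies) .AA_FREQ else NULL
  consensus <- sample(.AA20, L, replace = TRUE, prob = prob)
  rates <- rep(spec$substitutionRate, L)
  if (!is.null(spec$conservedBlocks))
    for (i in seq_len(nrow(spec$conservedBlocks))) {
      blk <- spec$conservedBlocks[i, ]
      rates[blk$start:blk$end] <- blk$rate
    }
  seqs <- character(spec$nSequences)
  for (s in seq_len(spec$nSequences)) {
    chars <- consensus
    mut <- which(stats::runif(L) < rates)
    for (p in mut)
      chars[p] <- sample(setdiff(.AA20, consensus[p]), 1L)
    seqs[s] <- paste(chars, collapse = "")
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sprintf("%s_%d", spec$name, seq_len(spec$nSequences))
  S4Vectors::metadata(out) <- list(classLabel = spec$classLabel,
                                   consensus = paste(consensus,
                                                     collapse = ""))
  out
}

#' Generate a labeled multi-family dataset
#'
#' Concatenates independently drawn families and (optionally) writes the
#' exact formats the training CLI consumes: a FASTA file and a
#' two-column tab-separated label table (`id`, `class`).
#'
#' @param specs A list of [familySpec()]s (at least one per class for
#'   training use).
#' @param fastaPath,labelsPath Optional output paths.
#' @return A list with `sequences` (an [Biostrings::AAStringSet]) and
#'   `labels` (a `data.frame` with columns `id` and `class`).
#' @export
generateLabeledDataset <- function(specs, fastaPath = NULL,
                                   labelsPath = NULL) {
  stopifnot(length(specs) >= 1L)
  fams <- lapply(specs, generateFamily)
  seqs <- do.call(c, fams)
  labels <- unlist(lapply(seq_along(fams), function(i)
    rep(specs[[i]]$classLabel, length(fams[[i]]))))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record ids across families; use distinct family names")
  lab <- data.frame(id = names(seqs), class = labels,
                    stringsAsFactors = FALSE)
  if (!is.null(fastaPath)) saveFasta(seqs, fastaPath)
  if (!is.null(labelsPath))
    utils::write.table(lab, labelsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(sequences = seqs, labels = lab)
}

#' Read a two-column label table
#'
#' @param path Tab-separated file with columns `id` and `class`
#'   (`cas`/`noncas`).
#' @return A `data.frame` with columns `id` and `class`.
#' @export
readLabels <- function(path) {
  lab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "class") %in% names(lab)))
  lab
}

#' The desk-scale synthetic benchmark
#'
#' The fixed two-family dataset used throughout the package's tests and
#' reproduction script: one Cas family and one non-Cas family with
#' independent random consensi (default length 60), 100 sequences each,
#' substitution rate 0.1, and a rate-0.02 conserved block spanning the
#' second third of the Cas consensus, mimicking a conserved
#' nuclease-domain motif.
#'
#' @param rngSeed Base seed (default 1); the two families use `rngSeed`
#'   and `rngSeed + 1000`.
#' @param nPerClass Sequences per class (default 100).
#' @param consensusLength Consensus length (default 60).
#' @return As [generateLabeledDataset()].
#' @export
syntheticBenchmark <- function(rngSeed = 1L, nPerClass = 100L,
                               consensusLength = 60L) {
  blockStart <- as.integer(floor(consensusLength / 3) + 1L)
  blockEnd <- as.integer(min(consensusLength,
                             blockStart + floor(consensusLength / 4)))
  generateLabeledDataset(list(
    familySpec("casA", consensusLength, nPerClass, substitutionRate = 0.1,
               conservedBlocks = data.frame(start = blockStart,
                                            end = blockEnd, rate = 0.02),
               classLabel = "cas", rngSeed = rngSeed),
    familySpec("nonA", consensusLength, nPerClass, substitutionRate = 0.1,
               classLabel = "noncas", rngSeed = rngSeed + 1000L)))
}
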