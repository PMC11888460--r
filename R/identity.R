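# Local-alignment percent identity against a reference database; the
# novelty filter of the generative pipeline. Alignment is Smith-Waterman
# under BLOSUM62 with BLAST-style affine gap costs (open 11, extend 1);
# identity uses the BLAST "Identities" denominator: the full alignment
# length including gap columns.

.blosum62env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum62env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62env$mat <- e$BLOSUM62
  }
  .blosum62env$mat
}

#' Percent identity between two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 (gap open 11, extend 1);
#' identity is `100 * identical aligned positions / alignment length`,
#' with gap columns counted in the length. The measure is symmetric.
#'
#' @param a A single amino-acid sequence.
#' @param b A sequence, or a vector/[Biostrings::AAStringSet] of
#'   sequences, each aligned against `a`.
#' @return Percent identity in `[0, 100]`, one value per element of `b`.
#' @examples
#' pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL")
#' @export
pairwiseIdentity <- function(a, b) {
  a <- .asSequenceCharacter(a)
  b <- .asSequenceCharacter(b)
  stopifnot(length(a) == 1L)
  if (nchar(a) == 0L || any(nchar(b) == 0L))
    stop("sequences must be nonempty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(b),
    subject = Biostrings::AAString(a),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1")
}

#' Maximum identity of a sequence against a reference database
#'
#' @param sequence A single amino-acid sequence.
#' @param referenceDb An [Biostrings::AAStringSet] or character vector of
#'   known proteins.
#' @return The maximum [pairwiseIdentity()] over the database.
#' @export
maxIdentityToDb <- function(sequence, referenceDb) {
  db <- .asSequenceCharacter(referenceDb)
  if (length(db) == 0L) stop("reference database is empty")
  max(pairwiseIdentity(sequence, db))
}

#' Filter candidate sequences for novelty
#'
#' Computes each candidate's maximum percent identity against the
#' reference database and rejects candidates at or above the threshold
#' (the pipeline default keeps only designs under 50% identity to any
#' known protein).
#'
#' For a candidate ledger (the [S4Vectors::DataFrame] returned by
#' [generateCandidates()]) the `maxIdentityPercent` and `status` columns
#' are updated in rows carrying a decoded, scored sequence; other rows
#' are left untouched. For a plain character vector a new `DataFrame`
#' with columns `sequence`, `maxIdentityPercent` and `novel` is returned.
#'
#' @param candidates Candidate sequences or a candidate ledger.
#' @param referenceDb An [Biostrings::AAStringSet] or character vector.
#' @param identityThresholdPercent Rejection threshold (default 50).
#' @return Updated ledger or a new `DataFrame` (see Details).
#' @export
noveltyFilter <- function(candidates, referenceDb,
                          identityThresholdPercent = 50) {
  db <- .asSequenceCharacter(referenceDb)
  if (length(db) == 0L) stop("reference database is empty")
  if (is.character(candidates) || methods::is(candidates, "XStringSet")) {
    seqs <- .asSequenceCharacter(candidates)
    maxId <- vapply(seqs, maxIdentityToDb, numeric(1), referenceDb = db,
                    USE.NAMES = FALSE)
    return(S4Vectors::DataFrame(
      sequence = seqs, maxIdentityPercent = maxId,
      novel = maxId < identityThresholdPercent))
  }
  stopifnot(methods::is(candidates, "DataFrame"))
  scored <- which(candidates$status %in%
                    c("scored", "accepted", "rejected_similar") &
                    !is.na(candidates$sequence) &
                    nchar(candidates$sequence) > 0L)
  for (i in scored) {
    maxId <- maxIdentityToDb(candidates$sequence[i], db)
    candidates$maxIdentityPercent[i] <- maxId
    candidates$status[i] <- if (maxId >= identityThresholdPercent)
      "rejected_similar" else "accepted"
  }
  candidates
}
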