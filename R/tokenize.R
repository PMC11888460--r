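#' Amino-acid token vocabulary
#'
#' The fixed 24-symbol vocabulary used throughout the package: the 20
#' standard amino acids in IUPAC one-letter notation plus an unknown-residue
#' symbol `X` and three special tokens marking the start, the end and the
#' padded tail of an encoded sequence.
#'
#' Codes are: `<pad>` = 0, `<start>` = 1, `<end>` = 2, the standard residues
#' `A` through `Y` in alphabetical order = 3 to 22, and `X` = 23.
#'
#' @return A named integer vector of length 24 mapping each symbol to its
#'   code. The mapping is a bijection onto `0:23`.
#' @examples
#' v <- proteinVocabulary()
#' v[c("A", "C", "X", "<pad>")]
#' @export
proteinVocabulary <- function() {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  structure(c(0L, 1L, 2L, 3:22, 23L),
            names = c("<pad>", "<start>", "<end>", residues, "X"))
}

# symbols that are legal in input records but outside the 20 standard
# residues; they encode as X (code 23)
.nonStandardResidues <- c("B", "Z", "J", "U", "O")

.PAD <- 0L
.START <- 1L
.END <- 2L
.XCODE <- 23L

#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into an [Biostrings::AAStringSet], uppercasing
#' sequences and stripping alignment gap (`-`) and stop (`*`) characters.
#' A warning reports how many characters were removed.
#'
#' @param path Path to an existing FASTA file.
#' @return An [Biostrings::AAStringSet] named by the FASTA identifiers
#'   (first whitespace-delimited word of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acdef", ">b", "MK-VL*"), fa)
#' loadFasta(fa)
#' @export
loadFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(raw))
  cleaned <- gsub("[-*]", "", seqs)
  nStripped <- sum(nchar(seqs) - nchar(cleaned))
  if (nStripped > 0L)
    warning(sprintf("stripped %d gap/stop character(s) from %s",
                    nStripped, path))
  if (any(nchar(cleaned) == 0L)) {
    bad <- names(raw)[nchar(cleaned) == 0L]
    stop("record(s) with empty sequence after cleaning: ",
         paste(bad, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(raw))
  out <- Biostrings::AAStringSet(cleaned)
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param x A named [Biostrings::AAStringSet] or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

.asSequenceCharacter <- function(x) {
  if (methods::is(x, "XStringSet")) as.character(x)
  else if (is.character(x)) x
  else stop("expected an AAStringSet or character vector of sequences")
}

#' Encode protein sequences as fixed-length token matrices
#'
#' Each sequence becomes one row of length `maxLen` laid out as
#' `[<start>, residue codes..., <end>, <pad>...]` under the vocabulary of
#' [proteinVocabulary()]. Letters outside the 20 standard residues (`B`,
#' `Z`, `J`, `U`, `O`) encode as `X` (code 23) with a warning; any other
#' character is an error. Sequences longer than `maxLen - 2` are rejected
#' rather than truncated: the fixed length is chosen to cover the corpus,
#' so overflow signals bad input.
#'
#' @param x An [Biostrings::AAStringSet] or character vector of uppercase
#'   amino-acid sequences.
#' @param maxLen Total encoded length including the start and end tokens
#'   (default 1600).
#' @return An integer matrix with one row per sequence and `maxLen`
#'   columns, rownames taken from `names(x)`, with attribute
#'   `sourceLength` giving the residue count of each input.
#' @examples
#' encodeSequences(c(s1 = "AC"), maxLen = 6)
#' @export
encodeSequences <- function(x, maxLen = 1600L) {
  seqs <- .asSequenceCharacter(x)
  maxLen <- as.integer(maxLen)
  if (length(seqs) == 0L) stop("no sequences to encode")
  if (maxLen < 3L) stop("maxLen must be at least 3")
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence cannot be encoded")
  if (any(lens > maxLen - 2L))
    stop(sprintf("sequence length %d exceeds maxLen - 2 = %d; not truncating",
                 max(lens), maxLen - 2L))
  vocab <- proteinVocabulary()
  out <- matrix(.PAD, nrow = length(seqs), ncol = maxLen)
  nonStd <- 0L
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    codes <- unname(vocab[chars])
    unknown <- is.na(codes)
    if (any(unknown)) {
      bad <- chars[unknown]
      if (!all(bad %in% .nonStandardResidues))
        stop("invalid sequence character(s): ",
             paste(unique(bad[!bad %in% .nonStandardResidues]), collapse = ""))
      codes[unknown] <- .XCODE
      nonStd <- nonStd + sum(unknown)
    }
    out[i, seq_len(lens[i] + 2L)] <- c(.START, codes, .END)
  }
  if (nonStd > 0L)
    warning(sprintf("%d non-standard residue(s) (B/Z/J/U/O) encoded as X",
                    nonStd))
  storage.mode(out) <- "integer"
  rownames(out) <- names(seqs)
  attr(out, "sourceLength") <- lens
  out
}

#' Decode token matrices back to amino-acid strings
#'
#' Reads each row after the start token up to the first end token (or the
#' first pad, if no end token is present) and inverse-maps the codes
#' through [proteinVocabulary()]. Malformed streams are decoded leniently
#' with a warning rather than rejected: the decoder output of an untrained
#' model is exactly such a stream.
#'
#' @param tokens An integer matrix of codes in `0:23` (rows are sequences),
#'   or a single integer vector.
#' @return A character vector of decoded sequences.
#' @examples
#' decodeTokens(c(1L, 3L, 4L, 2L, 0L, 0L))
#' @export
decodeTokens <- function(tokens) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1L)
  if (any(tokens < 0L | tokens > 23L))
    stop("token codes must lie in 0..23")
  vocab <- proteinVocabulary()
  symbols <- names(vocab)[order(vocab)]   # symbols[code + 1]
  malformed <- FALSE
  out <- character(nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    row <- tokens[i, ]
    if (length(row) == 0L) { out[i] <- ""; next }
    if (row[1L] != .START) malformed <- TRUE
    body <- if (row[1L] == .START) row[-1L] else row
    stop_at <- which(body == .END | body == .PAD)
    if (length(stop_at) == 0L) {
      malformed <- TRUE
      payload <- body
    } else {
      if (body[stop_at[1L]] == .PAD) malformed <- TRUE
      payload <- if (stop_at[1L] == 1L) integer(0) else body[seq_len(stop_at[1L] - 1L)]
      if (length(stop_at) > 1L || stop_at[1L] < length(body)) {
        tail <- body[seq(stop_at[1L] + 1L, length(body))]
        if (length(tail) && any(tail != .PAD)) malformed <- TRUE
      }
    }
    # special tokens inside the payload are dropped leniently
    if (any(payload < 3L)) { malformed <- TRUE; payload <- payload[payload >= 3L] }
    out[i] <- paste(symbols[payload + 1L], collapse = "")
  }
  if (malformed)
    warning("malformed token stream(s) decoded leniently")
  out
}
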