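# IUPAC nucleotide alphabet: encoding, ambiguity-aware matching, suffix
# mismatch scoring. Everything downstream (consensus building, homopolymer
# correction, filtering) goes through these primitives.

# Canonical IUPAC order; index into this vector is the internal integer code.
IUPAC_LETTERS <- c("A", "C", "G", "T",
                   "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# 4-bit masks: A=1, C=2, G=4, T=8. A code's mask is the union of its bases.
.IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A|G
  Y = 10L, # C|T
  S = 6L,  # C|G
  W = 9L,  # A|T
  K = 12L, # G|T
  M = 3L,  # A|C
  B = 14L, # C|G|T
  D = 13L, # A|G|T
  H = 11L, # A|C|T
  V = 7L,  # A|C|G
  N = 15L
)[IUPAC_LETTERS]

# mask (1..15) -> symbol
.MASK_TO_LETTER <- character(15L)
.MASK_TO_LETTER[.IUPAC_MASKS] <- IUPAC_LETTERS

# 15x15 logical: do the base sets of two codes intersect?
.IUPAC_COMPAT <- outer(.IUPAC_MASKS, .IUPAC_MASKS,
                       function(a, b) bitwAnd(a, b) > 0L)
dimnames(.IUPAC_COMPAT) <- list(IUPAC_LETTERS, IUPAC_LETTERS)

#' List the bases denoted by an IUPAC symbol
#'
#' @param code A single IUPAC nucleotide symbol.
#' @return Character vector, a subset of `c("A","C","G","T")`.
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(code) {
  idx <- .encode_seq(code, what = "code")
  mask <- .IUPAC_MASKS[idx]
  c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Ambiguity-aware base/code matching
#'
#' A base matches a code when it belongs to the code's base set. Both
#' arguments may be ambiguity codes, in which case they match when their
#' base sets intersect (the weakest rule consistent with set semantics;
#' needed because gap filling can write ambiguity codes into reads).
#'
#' @param base Character vector of nucleotides (or codes), recycled.
#' @param code Character vector of IUPAC symbols, recycled.
#' @return Logical vector.
#' @examples
#' iupac_matches("A", "R")  # TRUE:  R = {A,G}
#' iupac_matches("C", "R")  # FALSE
#' @export
iupac_matches <- function(base, code) {
  b <- .encode_seq(paste(base, collapse = ""), what = "base")
  k <- .encode_seq(paste(code, collapse = ""), what = "code")
  n <- max(length(b), length(k))
  .IUPAC_COMPAT[cbind(rep_len(b, n), rep_len(k, n))]
}

#' The IUPAC symbol for a set of bases
#'
#' @param bases Nonempty character vector drawn from `c("A","C","G","T")`
#'   (duplicates allowed), or a vector of IUPAC codes whose base sets are
#'   pooled.
#' @return A single IUPAC symbol whose base set is the union of the input.
#' @examples
#' ambiguity_for(c("A", "G"))  # "R"
#' @export
ambiguity_for <- function(bases) {
  if (length(bases) == 0L) stop("ambiguity_for(): empty base set")
  idx <- .encode_seq(paste(bases, collapse = ""), what = "base")
  mask <- Reduce(bitwOr, .IUPAC_MASKS[idx])
  .MASK_TO_LETTER[mask]
}

# --- internal encoding -------------------------------------------------------

# Character string -> integer codes (1..15). Uppercases; rejects U and any
# non-IUPAC character, naming the character and its position.
.encode_seq <- function(s, what = "sequence") {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  idx <- match(chars, IUPAC_LETTERS)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop(sprintf("invalid %s character '%s' at position %d (DNA IUPAC alphabet only)",
                 what, chars[p], p))
  }
  idx
}

.decode_seq <- function(idx) paste(IUPAC_LETTERS[idx], collapse = "")

# Positional mismatch flags of an encoded read against encoded consensus
# columns of the same length (TRUE = base sets disjoint).
.mismatch_flags <- function(r_idx, c_idx) {
  !.IUPAC_COMPAT[cbind(r_idx, c_idx)]
}

# --- consensus reference container ------------------------------------------

#' Construct a consensus reference
#'
#' A consensus reference is a sequence over the IUPAC alphabet used as a
#' positional anchor: read position 1 is compared against consensus position
#' `offset + 1`, with no realignment.
#'
#' @param sequence IUPAC string (no gaps).
#' @param offset Non-negative integer; consensus position preceding read
#'   position 1. Default 0 (reads register at the consensus start).
#' @return An object of class `consensus_ref`.
#' @export
consensus_ref <- function(sequence, offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L,
            offset >= 0L)
  idx <- .encode_seq(sequence, what = "consensus")
  structure(list(sequence = .decode_seq(idx), offset = as.integer(offset)),
            class = "consensus_ref")
}

#' @export
print.consensus_ref <- function(x, ...) {
  cat(sprintf("consensus_ref: %d nt, offset %d\n", nchar(x$sequence), x$offset))
  s <- x$sequence
  cat(if (nchar(s) > 60L) paste0(substr(s, 1L, 60L), "...") else s, "\n")
  invisible(x)
}

.as_consensus <- function(consensus) {
  if (inherits(consensus, "consensus_ref")) consensus
  else consensus_ref(consensus)
}

# Encoded consensus columns available to a read: positions offset+1 .. end.
.consensus_columns <- function(consensus) {
  idx <- .encode_seq(consensus$sequence, what = "consensus")
  if (consensus$offset >= length(idx))
    stop("consensus offset leaves no reference columns for the read")
  idx[(consensus$offset + 1L):length(idx)]
}

#' Suffix mismatch counts of a read against the consensus
#'
#' Position `i` of the result is the number of ambiguity-aware mismatches
#' from read position `i` through the read end, compared positionally
#' against the consensus (no realignment). This is the alignment score used
#' to detect and accept homopolymer corrections.
#'
#' @param read DNA/IUPAC string.
#' @param consensus A `consensus_ref` (or plain IUPAC string, offset 0).
#' @return Integer vector, one entry per read position; non-increasing.
#' @examples
#' suffix_mismatch_counts("ATTT", "ATTG")  # 1 1 1 1
#' @export
suffix_mismatch_counts <- function(read, consensus) {
  consensus <- .as_consensus(consensus)
  r <- .encode_seq(read, what = "read")
  cols <- .consensus_columns(consensus)
  if (length(r) > length(cols))
    stop(sprintf("read (%d nt) overhangs the consensus by %d nt beyond offset %d",
                 length(r), length(r) - length(cols), consensus$offset))
  mm <- .mismatch_flags(r, cols[seq_along(r)])
  rev(cumsum(rev(as.integer(mm))))
}

# Tolerant mismatch flags used internally by the corrector: read positions
# beyond the consensus coverage count as mismatches instead of erroring, so
# a read lengthened by an insertion error can still be scored and repaired.
.mismatch_flags_tolerant <- function(r_idx, cols) {
  n <- length(r_idx)
  k <- min(n, length(cols))
  flags <- rep(TRUE, n)
  if (k > 0L) flags[seq_len(k)] <- .mismatch_flags(r_idx[seq_len(k)], cols[seq_len(k)])
  flags
}
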