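# Step 2: build an IUPAC-ambiguity consensus reference from a multiple
# alignment of reference sequences (union semantics, as produced by
# EMBOSS-style ambiguity consensus tools).

#' Build an IUPAC consensus reference from an alignment
#'
#' Per column, every row symbol is expanded to its base set (input ambiguity
#' codes are pooled), gap characters are ignored, bases whose column
#' frequency falls below `min_state_freq` are dropped, and the IUPAC symbol
#' for the union of surviving bases is emitted. A column that is all gaps,
#' or where every base is dropped, yields `N`.
#'
#' @param alignment Character vector of equal-length aligned IUPAC rows
#'   (`-` allowed), or an `XStringSet`.
#' @param min_state_freq Minimum fraction of non-gap rows a base must reach
#'   to enter the consensus. Default 0 (pure union). Nonzero values guard
#'   against large alignments degenerating toward an all-N consensus.
#' @param offset Offset stored on the returned reference (default 0).
#' @return A `consensus_ref`.
#' @examples
#' build_consensus(c("AAG", "AAT"))  # consensus "AAK"
#' @export
build_consensus <- function(alignment, min_state_freq = 0, offset = 0L) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (length(alignment) == 0L) stop("empty alignment")
  alignment <- toupper(alignment)
  width <- unique(nchar(alignment))
  if (length(width) != 1L) stop("alignment rows differ in length")
  if (width == 0L) stop("alignment rows are empty")

  chars <- matrix(unlist(strsplit(alignment, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(alignment), ncol = width, byrow = TRUE)
  gap <- chars == "-" | chars == "."
  idx <- match(chars, IUPAC_LETTERS)
  if (any(is.na(idx) & !gap)) {
    bad <- which(is.na(idx) & !gap)[1L]
    stop(sprintf("invalid alignment character '%s'", chars[bad]))
  }
  masks <- matrix(0L, nrow = nrow(chars), ncol = width)
  masks[!gap] <- .IUPAC_MASKS[idx[!gap]]

  bits <- c(1L, 2L, 4L, 8L)
  out <- vapply(seq_len(width), function(j) {
    m <- masks[, j]
    m <- m[m > 0L]
    if (length(m) == 0L) return("N")
    counts <- vapply(bits, function(b) sum(bitwAnd(m, b) > 0L), 0L)
    keep <- counts > 0L & (counts / length(m)) >= min_state_freq
    mask <- sum(bits[keep])
    if (mask == 0L) "N" else .MASK_TO_LETTER[mask]
  }, "")
  consensus_ref(paste(out, collapse = ""), offset = offset)
}

#' Read an aligned FASTA and build its consensus
#'
#' @param path Aligned FASTA file.
#' @inheritParams build_consensus
#' @return A `consensus_ref`.
#' @export
consensus_from_fasta <- function(path, min_state_freq = 0, offset = 0L) {
  aln <- read_fasta(path)
  build_consensus(aln$sequence, min_state_freq = min_state_freq, offset = offset)
}

#' Write a consensus reference as single-record FASTA
#'
#' @param consensus A `consensus_ref`.
#' @param path Output path.
#' @param id Record id (default "consensus").
#' @export
write_consensus <- function(consensus, path, id = "consensus") {
  write_fasta(data.frame(id = id, sequence = consensus$sequence,
                         stringsAsFactors = FALSE), path)
}
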