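# Step 4: singleton exclusion, consensus-divergence filtering, 3' trimming,
# and ambiguity-consistent merging of unique sequences.

#' Drop low-frequency unique sequences
#'
#' Singletons (and, with a higher `min_count`, other rare sequences) are
#' excluded a priori as likely uninformative before consensus filtering.
#'
#' @param uniques Unique-sequence data.frame.
#' @param min_count Minimum retained read count (default 2: singletons go).
#' @return List with `uniques` and `removed` (number of rows dropped).
#' @export
drop_low_count <- function(uniques, min_count = 2L) {
  keep <- uniques$count >= min_count
  list(uniques = .order_uniques(uniques[keep, , drop = FALSE]),
       removed = sum(!keep))
}

#' Trim and filter unique sequences against the consensus
#'
#' Each sequence is truncated to its first `trim_to` bases (homopolymer
#' correction loses power toward the 3' end, where fewer downstream anchor
#' positions remain) and retained only if its ambiguity-aware mismatch count
#' to the consensus over those positions is at most `max_mismatch`.
#' Sequences shorter than `trim_to` are removed.
#'
#' @param uniques Unique-sequence data.frame.
#' @param consensus `consensus_ref` or IUPAC string.
#' @param max_mismatch Permitted consensus mismatches (default 1).
#' @param trim_to Retained alignment length (default 220).
#' @return List with `uniques` (trimmed survivors), `removed_divergent`,
#'   and `removed_short`.
#' @export
consensus_filter <- function(uniques, consensus, max_mismatch = 1L, trim_to = 220L) {
  consensus <- .as_consensus(consensus)
  cols <- .consensus_columns(consensus)
  if (trim_to > length(cols))
    stop(sprintf("trim_to (%d) exceeds available consensus columns (%d)",
                 trim_to, length(cols)))
  cols <- cols[seq_len(trim_to)]
  long_enough <- nchar(uniques$sequence) >= trim_to
  u <- uniques[long_enough, , drop = FALSE]
  u$sequence <- substr(u$sequence, 1L, trim_to)
  mm <- vapply(u$sequence, function(s) {
    sum(.mismatch_flags(.encode_seq(s, "read"), cols))
  }, 0L, USE.NAMES = FALSE)
  keep <- mm <= max_mismatch
  list(uniques = .order_uniques(u[keep, , drop = FALSE]),
       removed_divergent = sum(!keep),
       removed_short = sum(!long_enough))
}

# Are two equal-length encoded sequences compatible at every position
# (identical except where an ambiguity code covers the other's base)?
.all_compatible <- function(a_idx, b_idx) {
  all(.IUPAC_COMPAT[cbind(a_idx, b_idx)])
}

# Positionwise resolution of two compatible sequences: intersection of the
# base sets, so unambiguous states win over ambiguity codes.
.resolve_pair <- function(a_idx, b_idx) {
  mask <- bitwAnd(.IUPAC_MASKS[a_idx], .IUPAC_MASKS[b_idx])
  match(.MASK_TO_LETTER[mask], IUPAC_LETTERS)
}

#' Merge ambiguity-consistent unique sequences
#'
#' Sequences identical except at positions where one carries an ambiguity
#' code consistent with the other's base are treated as identical: the
#' lower-count sequence is merged into the highest-count compatible target
#' (ties by name), unambiguous states win, and counts are summed. Repeated
#' to a fixpoint.
#'
#' @param uniques Unique-sequence data.frame; all sequences must have equal
#'   length (run after trimming).
#' @return List with `uniques` and `merged` (number of merge events).
#' @export
merge_ambiguity_consistent <- function(uniques) {
  if (nrow(uniques) == 0L) return(list(uniques = uniques, merged = 0L))
  if (length(unique(nchar(uniques$sequence))) != 1L)
    stop("merge requires equal-length sequences (trim first)")
  n_merged <- 0L
  u <- .order_uniques(uniques)
  repeat {
    changed <- FALSE
    enc <- lapply(u$sequence, .encode_seq, what = "read")
    accepted <- integer(0)  # row indices into u, in acceptance order
    merged_away <- logical(nrow(u))
    for (k in seq_len(nrow(u))) {
      target <- NA_integer_
      for (a in accepted) {  # accepted is in descending-count order
        if (.all_compatible(enc[[k]], enc[[a]])) { target <- a; break }
      }
      if (is.na(target)) {
        accepted <- c(accepted, k)
      } else {
        enc[[target]] <- .resolve_pair(enc[[target]], enc[[k]])
        u$count[target] <- u$count[target] + u$count[k]
        merged_away[k] <- TRUE
        n_merged <- n_merged + 1L
        changed <- TRUE
      }
    }
    u <- u[!merged_away, , drop = FALSE]
    u$sequence <- vapply(enc[!merged_away], .decode_seq, "")
    u <- dereplicate(u)  # resolution may have made rows identical
    if (!changed) break
  }
  list(uniques = .order_uniques(u), merged = n_merged)
}
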