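# Step 5: remove low-frequency sequences near-identical to a
# higher-frequency sequence in the same pool (PCR error, sequencing error,
# or numt proxies that survive the consensus filter).

# Ambiguity-aware Hamming distance between two equal-length encoded
# sequences (compatible positions count as matches).
.hamming_compat <- function(a_idx, b_idx) {
  sum(!.IUPAC_COMPAT[cbind(a_idx, b_idx)])
}

#' Frequency filter against retained higher-count neighbours
#'
#' Sequences are processed in descending count order (ties by name). A
#' sequence is removed when an already-retained sequence lies within
#' `floor(max_divergence * L)` ambiguity-aware mismatches of it and its
#' count is below `min_freq_ratio` times that sequence's count; otherwise it
#' is retained. The most frequent sequence overall is therefore always
#' retained, and the outcome does not depend on input order. Comparison is
#' against retained sequences only, which prevents chained removals below an
#' already-removed sequence.
#'
#' @param uniques Unique-sequence data.frame; equal-length sequences.
#' @param max_divergence Divergence threshold as a fraction of the sequence
#'   length (default 0.01, i.e. 2 mismatches at 220 nt).
#' @param min_freq_ratio Frequency threshold relative to the retained
#'   neighbour (default 0.10).
#' @return List with `retained` (unique-sequence data.frame) and `removed`
#'   (data.frame of `name`, `count`, `neighbor`, `distance`, `ratio`).
#' @export
frequency_filter <- function(uniques, max_divergence = 0.01, min_freq_ratio = 0.10) {
  stopifnot(max_divergence >= 0, max_divergence <= 1,
            min_freq_ratio > 0, min_freq_ratio <= 1)
  empty_removed <- data.frame(name = character(), count = integer(),
                              neighbor = character(), distance = integer(),
                              ratio = numeric(), stringsAsFactors = FALSE)
  if (nrow(uniques) == 0L)
    return(list(retained = uniques, removed = empty_removed))
  L <- unique(nchar(uniques$sequence))
  if (length(L) != 1L) stop("frequency filter requires equal-length sequences")
  thr <- floor(max_divergence * L)

  u <- .order_uniques(uniques)
  enc <- lapply(u$sequence, .encode_seq, what = "read")
  retained <- integer(0)
  removed <- vector("list", nrow(u))
  for (k in seq_len(nrow(u))) {
    hit <- NA_integer_
    hit_d <- NA_integer_
    for (a in retained) {
      if (u$count[k] >= min_freq_ratio * u$count[a]) next
      d <- .hamming_compat(enc[[k]], enc[[a]])
      if (d <= thr) { hit <- a; hit_d <- d; break }
    }
    if (is.na(hit)) {
      retained <- c(retained, k)
    } else {
      removed[[k]] <- data.frame(
        name = u$name[k], count = u$count[k], neighbor = u$name[hit],
        distance = hit_d, ratio = u$count[k] / u$count[hit],
        stringsAsFactors = FALSE)
    }
  }
  removed <- removed[!vapply(removed, is.null, TRUE)]
  list(retained = u[retained, , drop = FALSE],
       removed = if (length(removed)) do.call(rbind, removed) else empty_removed)
}
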