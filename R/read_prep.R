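# Step 1: forward-primer trimming, length filtering/truncation, and
# dereplication of reads into count-annotated unique sequences.

#' Trim the forward primer from reads
#'
#' Reads whose prefix does not match the primer under ambiguity-aware
#' matching (allowing `max_mismatch` mismatching positions) are dropped and
#' counted. `trim_length` controls how many bases are removed from matching
#' reads: `"full"` removes the whole primer; an integer removes exactly that
#' many bases (useful when upstream demultiplexing already consumed part of
#' the primer region).
#'
#' @param reads Read data.frame (`id`, `sequence`).
#' @param primer IUPAC primer string.
#' @param trim_length `"full"` (default) or a positive integer.
#' @param max_mismatch Allowed primer mismatches (default 0).
#' @return List with `reads` (trimmed survivors, order preserved) and
#'   `dropped` (number of reads removed).
#' @export
trim_primer <- function(reads, primer, trim_length = "full", max_mismatch = 0L) {
  p_idx <- .encode_seq(primer, what = "primer")
  plen <- length(p_idx)
  if (identical(trim_length, "full")) trim_length <- plen
  trim_length <- as.integer(trim_length)
  if (trim_length < 1L) stop("trim_length must be a positive integer or \"full\"")

  keep <- logical(nrow(reads))
  out <- character(nrow(reads))
  for (k in seq_len(nrow(reads))) {
    s <- reads$sequence[k]
    n <- nchar(s)
    if (n < plen || n < trim_length) next
    r_idx <- .encode_seq(substr(s, 1L, plen), what = "read")
    if (sum(.mismatch_flags(r_idx, p_idx)) <= max_mismatch) {
      keep[k] <- TRUE
      out[k] <- substr(s, trim_length + 1L, n)
    }
  }
  keep <- keep & nzchar(out)
  res <- reads[keep, , drop = FALSE]
  res$sequence <- out[keep]
  row.names(res) <- NULL
  list(reads = res, dropped = sum(!keep))
}

#' Length-filter and truncate reads
#'
#' Reads shorter than `min_length` (measured after primer trimming) are
#' removed; reads longer than `max_length` are truncated to `max_length`.
#'
#' @param reads Read data.frame.
#' @param min_length Minimum retained length (default 170; a 170-nt read is
#'   kept).
#' @param max_length Truncation length (default 300).
#' @return List with `reads`, `removed` (count below minimum) and
#'   `truncated` (count shortened).
#' @export
filter_and_truncate <- function(reads, min_length = 170L, max_length = 300L) {
  if (min_length > max_length)
    stop(sprintf("min_length (%d) exceeds max_length (%d)", min_length, max_length))
  len <- nchar(reads$sequence)
  keep <- len >= min_length
  res <- reads[keep, , drop = FALSE]
  long <- nchar(res$sequence) > max_length
  res$sequence[long] <- substr(res$sequence[long], 1L, max_length)
  row.names(res) <- NULL
  list(reads = res, removed = sum(!keep), truncated = sum(long))
}

#' Dereplicate reads into unique sequences
#'
#' Collapses exact sequence duplicates. For raw reads each read counts 1 and
#' the group takes the id of its first member; for an already-dereplicated
#' table (a `count` column present) counts are treated as weights and summed,
#' so the operation can be reapplied after correction merges sequences.
#' Output is sorted by descending count, ties broken by name.
#'
#' @param x Read data.frame (`id`, `sequence`) or unique-sequence table
#'   (`name`, `count`, `sequence`).
#' @return Unique-sequence data.frame (`name`, `count`, `sequence`).
#' @export
dereplicate <- function(x) {
  if (!"count" %in% names(x)) {
    # raw reads: group in input order, representative = first member's id
    x <- .uniques(name = x$id, count = rep(1L, nrow(x)), sequence = x$sequence)
  } else {
    # weighted rerun: representative = highest-count member, ties by name
    x <- .order_uniques(x)
  }
  grp <- match(x$sequence, unique(x$sequence))
  counts <- as.integer(rowsum(x$count, grp)[, 1L])  # rowsum sorts by group id,
  first <- !duplicated(grp)                         # which is appearance order
  .order_uniques(.uniques(name = x$name[first], count = counts,
                          sequence = x$sequence[first]))
}
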