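# Step 6 support: advisory flagging of uncorrected compensated indels and
# putative numts for manual review. Flags never remove sequences by
# themselves; removal is an explicit opt-in.

.no_flags <- function() {
  data.frame(name = character(), kind = character(), partner = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' Flag putative uncorrected compensated indels
#'
#' A surviving compensated indel shows up as a sequence differing from a
#' related higher-count sequence only within one contiguous run of
#' mismatching positions.
#'
#' @param uniques Unique-sequence data.frame; equal-length sequences.
#' @param min_run Minimum length of the contiguous mismatch run (default 3).
#' @return Flag data.frame (`name`, `kind`, `partner`, `evidence`).
#' @export
flag_compensated_indels <- function(uniques, min_run = 3L) {
  if (nrow(uniques) < 2L) return(.no_flags())
  if (length(unique(nchar(uniques$sequence))) != 1L)
    stop("flagging requires equal-length sequences")
  u <- .order_uniques(uniques)
  enc <- lapply(u$sequence, .encode_seq, what = "read")
  flags <- vector("list", nrow(u))
  for (k in seq_len(nrow(u))) {
    for (a in seq_len(nrow(u))) {
      if (u$count[a] <= u$count[k]) next
      d <- which(!.IUPAC_COMPAT[cbind(enc[[k]], enc[[a]])])
      if (length(d) >= min_run && (max(d) - min(d) + 1L) == length(d)) {
        flags[[k]] <- data.frame(
          name = u$name[k], kind = "compensated_indel", partner = u$name[a],
          evidence = sprintf("run of %d mismatches at %d-%d vs count %d",
                             length(d), min(d), max(d), u$count[a]),
          stringsAsFactors = FALSE)
        break  # highest-count qualifying partner (u is count-sorted)
      }
    }
  }
  flags <- flags[!vapply(flags, is.null, TRUE)]
  if (length(flags)) do.call(rbind, flags) else .no_flags()
}

#' Flag putative numts
#'
#' Nuclear mitochondrial pseudogenes that pass the consensus filter tend to
#' appear as low-frequency variants phylogenetically close to a target
#' sequence. A sequence is flagged when some partner has at least
#' `1 / max_freq_ratio` times its count and lies within `max_divergence`
#' p-distance; all qualifying partners are listed on the flag.
#'
#' @param uniques Unique-sequence data.frame; equal-length sequences.
#' @param max_divergence Maximum p-distance to the partner (default 0.10).
#' @param max_freq_ratio Count ratio below which a sequence qualifies
#'   (default 0.10).
#' @return Flag data.frame (`name`, `kind`, `partner`, `evidence`); multiple
#'   partners are comma-separated in `partner`.
#' @export
flag_putative_numts <- function(uniques, max_divergence = 0.10,
                                max_freq_ratio = 0.10) {
  if (nrow(uniques) < 2L) return(.no_flags())
  L <- unique(nchar(uniques$sequence))
  if (length(L) != 1L) stop("flagging requires equal-length sequences")
  u <- .order_uniques(uniques)
  enc <- lapply(u$sequence, .encode_seq, what = "read")
  flags <- vector("list", nrow(u))
  for (k in seq_len(nrow(u))) {
    partners <- character(0)
    details <- character(0)
    for (a in seq_len(nrow(u))) {
      if (a == k) next
      if (u$count[k] >= max_freq_ratio * u$count[a]) next
      d <- .hamming_compat(enc[[k]], enc[[a]])
      if (d / L <= max_divergence) {
        partners <- c(partners, u$name[a])
        details <- c(details, sprintf("%s: p-dist %.3f, ratio %.3f",
                                      u$name[a], d / L, u$count[k] / u$count[a]))
      }
    }
    if (length(partners)) {
      flags[[k]] <- data.frame(
        name = u$name[k], kind = "putative_numt",
        partner = paste(partners, collapse = ","),
        evidence = paste(details, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  flags <- flags[!vapply(flags, is.null, TRUE)]
  if (length(flags)) do.call(rbind, flags) else .no_flags()
}

#' Drop flagged sequences from a unique-sequence table
#'
#' @param uniques Unique-sequence data.frame.
#' @param flags Flag data.frame from [flag_compensated_indels()] or
#'   [flag_putative_numts()].
#' @return Unique-sequence data.frame without the flagged names.
#' @export
drop_flagged <- function(uniques, flags) {
  .order_uniques(uniques[!(uniques$name %in% flags$name), , drop = FALSE])
}
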