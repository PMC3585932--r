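# Step 3: per-read correction of homopolymer insertion errors, deletion
# errors, and compensated indels against the consensus reference.
#
# All passes share the same acceptance rule: an edit is kept only if the
# total ambiguity-aware mismatch count to the consensus strictly decreases.
# The mismatch vector is recomputed after every accepted edit and scanning
# resumes at the edit site, so the procedure is deterministic and cannot
# loop. Internally, read positions beyond the consensus coverage are scored
# as mismatches so that a read lengthened by an insertion error can still
# be repaired against a same-length reference.

.total_mm <- function(r, cols) sum(.mismatch_flags_tolerant(r, cols))

.event_row <- function(read_name, kind, position, before, after) {
  data.frame(read_name = read_name, kind = kind, position = as.integer(position),
             before = before, after = after, stringsAsFactors = FALSE)
}

.no_events <- function() {
  data.frame(read_name = character(), kind = character(), position = integer(),
             before = character(), after = character(), stringsAsFactors = FALSE)
}

# --- insertion errors --------------------------------------------------------

# Scan 5'->3'; at each mismatch position i with a homopolymer run (>= 2
# identical bases) ending at i-1, tentatively delete one base of the run;
# keep the deletion iff the total mismatch count strictly decreases.
.pass_insertions <- function(r, cols, read_name, max_events) {
  events <- list()
  pos <- 1L
  score <- .total_mm(r, cols)
  while (score > 0L && length(events) < max_events) {
    flags <- .mismatch_flags_tolerant(r, cols)
    nxt <- which(flags)
    nxt <- nxt[nxt >= pos]
    if (length(nxt) == 0L) break
    i <- nxt[1L]
    accepted <- FALSE
    if (i >= 3L && r[i - 1L] == r[i - 2L]) {
      cand <- r[-(i - 1L)]
      s2 <- .total_mm(cand, cols)
      if (s2 < score) {
        events[[length(events) + 1L]] <-
          .event_row(read_name, "insertion_removed", i - 1L,
                     IUPAC_LETTERS[r[i - 1L]], "")
        r <- cand
        score <- s2
        pos <- max(1L, i - 2L)
        accepted <- TRUE
      }
    }
    if (!accepted) pos <- i + 1L
  }
  list(r = r, events = events)
}

# --- deletion errors ---------------------------------------------------------

# Gap-fill symbol for a single gap given its flanking read symbols and the
# consensus column: extend the left homopolymer if consistent, else the
# right, else write the consensus symbol itself (which may be ambiguous).
.fill_deletion <- function(left, right, gapcol) {
  l_ok <- !is.na(left) && .IUPAC_COMPAT[left, gapcol]
  r_ok <- !is.na(right) && .IUPAC_COMPAT[right, gapcol]
  if (l_ok) left else if (r_ok) right else gapcol
}

# At each mismatch position i, tentatively insert one base before i
# (shifting the suffix right; bases pushed past max_length are discarded);
# keep iff the total mismatch count strictly decreases.
.pass_deletions <- function(r, cols, read_name, max_events, max_length) {
  events <- list()
  pos <- 1L
  score <- .total_mm(r, cols)
  while (score > 0L && length(events) < max_events) {
    flags <- .mismatch_flags_tolerant(r, cols)
    nxt <- which(flags)
    nxt <- nxt[nxt >= pos]
    if (length(nxt) == 0L) break
    i <- nxt[1L]
    if (i > length(cols)) { pos <- i + 1L; next }  # overhang: no column to fill
    X <- .fill_deletion(if (i > 1L) r[i - 1L] else NA_integer_, r[i], cols[i])
    cand <- append(r, X, after = i - 1L)
    if (length(cand) > max_length) cand <- cand[seq_len(max_length)]
    s2 <- .total_mm(cand, cols)
    if (s2 < score) {
      events[[length(events) + 1L]] <-
        .event_row(read_name, "deletion_filled", i, "", IUPAC_LETTERS[X])
      r <- cand
      score <- s2
      pos <- i
    } else {
      pos <- i + 1L
    }
  }
  list(r = r, events = events)
}

# --- compensated indels ------------------------------------------------------

# Gap-fill for compensation: if exactly one flank is consistent with the
# consensus column, extend it; if both or neither qualify, write the
# ambiguity code pooling the flanking bases.
.fill_compensation <- function(left, right, gapcol) {
  l_ok <- !is.na(left) && .IUPAC_COMPAT[left, gapcol]
  r_ok <- !is.na(right) && .IUPAC_COMPAT[right, gapcol]
  if (l_ok && !r_ok) return(left)
  if (r_ok && !l_ok) return(right)
  both <- c(left, right)
  both <- both[!is.na(both)]
  if (length(both) == 0L) return(gapcol)
  mask <- Reduce(bitwOr, .IUPAC_MASKS[IUPAC_LETTERS[both]])
  match(.MASK_TO_LETTER[mask], IUPAC_LETTERS)
}

# Position of a removable homopolymer base at a site: the run containing
# the site, or the run immediately preceding it; NA when no run (>= 2) is
# adjacent.
.hp_del_pos <- function(r, site) {
  n <- length(r)
  if (site >= 1L && site <= n) {
    if ((site < n && r[site] == r[site + 1L]) ||
        (site > 1L && r[site] == r[site - 1L])) return(site)
  }
  if (site >= 3L && site <= n + 1L && r[site - 1L] == r[site - 2L]) return(site - 1L)
  NA_integer_
}

# One candidate repair for a mismatch region [i, j]:
#  - orientation "del_at_i": remove a homopolymer base at the i end, then
#    insert a filled gap at position j (read length unchanged);
#  - orientation "gap_at_i": insert a filled gap at position i, then remove
#    a homopolymer base at the (shifted) j end.
.comp_candidate <- function(r, cols, i, j, orientation, max_length) {
  if (orientation == "del_at_i") {
    dp <- .hp_del_pos(r, i)
    if (is.na(dp) || dp >= j) return(NULL)
    r2 <- r[-dp]
    if (j > length(r2) + 1L || j > length(cols)) return(NULL)
    X <- .fill_compensation(if (j > 1L) r2[j - 1L] else NA_integer_,
                            if (j <= length(r2)) r2[j] else NA_integer_,
                            cols[j])
    cand <- append(r2, X, after = j - 1L)
  } else {
    if (i > length(cols)) return(NULL)
    X <- .fill_compensation(if (i > 1L) r[i - 1L] else NA_integer_, r[i], cols[i])
    r2 <- append(r, X, after = i - 1L)
    dp <- .hp_del_pos(r2, j + 1L)
    if (is.na(dp) || dp <= i) return(NULL)
    cand <- r2[-dp]
  }
  if (length(cand) > max_length) cand <- cand[seq_len(max_length)]
  cand
}

# Identify a mismatch region with > 1 mismatch inside and at most one
# mismatched position upstream/downstream, try both indel orientations on
# the candidate region bounds, and accept the best strict improvement.
.pass_compensated <- function(r, cols, read_name, max_events, max_length) {
  events <- list()
  repeat {
    if (length(events) >= max_events) break
    flags <- .mismatch_flags_tolerant(r, cols)
    P <- which(flags)
    M <- length(P)
    if (M < 2L) break
    score <- M
    # region bounds: first/last mismatch, optionally sparing one isolated
    # mismatch on either side
    ab <- unique(rbind(c(1L, M),
                       if (M >= 3L) c(2L, M),
                       if (M >= 3L) c(1L, M - 1L),
                       if (M >= 4L) c(2L, M - 1L)))
    best_s <- score
    best <- NULL
    for (k in seq_len(nrow(ab))) {
      i <- P[ab[k, 1L]]
      j <- P[ab[k, 2L]]
      for (orientation in c("del_at_i", "gap_at_i")) {
        cand <- .comp_candidate(r, cols, i, j, orientation, max_length)
        if (is.null(cand)) next
        s2 <- .total_mm(cand, cols)
        if (s2 < best_s) {
          best_s <- s2
          best <- list(cand = cand, i = i, j = j)
        }
      }
    }
    if (is.null(best)) break
    jj <- min(best$j, length(best$cand), length(r))
    events[[length(events) + 1L]] <-
      .event_row(read_name, "compensation", best$i,
                 .decode_seq(r[best$i:min(best$j, length(r))]),
                 .decode_seq(best$cand[best$i:jj]))
    r <- best$cand
  }
  list(r = r, events = events)
}

# --- combined sitewise pass --------------------------------------------------

# Walk mismatch positions 5'->3'; at each site build both the
# insertion-removal and the deletion-fill candidate and apply whichever
# decreases the total mismatch count most (ties prefer insertion removal).
# Competing the two repairs at one site is essential: a read carrying a
# deletion error frameshifts its whole suffix, and against that noisy
# background a spurious homopolymer removal elsewhere can strictly improve
# the score by chance; the true gap fill improves it far more and wins.
.pass_sitewise <- function(r, cols, read_name, max_events, max_length) {
  events <- list()
  pos <- 1L
  score <- .total_mm(r, cols)
  while (score > 0L && length(events) < max_events) {
    flags <- .mismatch_flags_tolerant(r, cols)
    nxt <- which(flags)
    nxt <- nxt[nxt >= pos]
    if (length(nxt) == 0L) break
    i <- nxt[1L]

    s_ins <- Inf
    cand_ins <- NULL
    if (i >= 3L && r[i - 1L] == r[i - 2L]) {
      cand_ins <- r[-(i - 1L)]
      s_ins <- .total_mm(cand_ins, cols)
    }
    s_del <- Inf
    cand_del <- NULL
    X <- NA_integer_
    if (i <= length(cols)) {
      X <- .fill_deletion(if (i > 1L) r[i - 1L] else NA_integer_, r[i], cols[i])
      cand_del <- append(r, X, after = i - 1L)
      if (length(cand_del) > max_length) cand_del <- cand_del[seq_len(max_length)]
      s_del <- .total_mm(cand_del, cols)
    }

    if (s_ins < score && s_ins <= s_del) {
      events[[length(events) + 1L]] <-
        .event_row(read_name, "insertion_removed", i - 1L,
                   IUPAC_LETTERS[r[i - 1L]], "")
      r <- cand_ins
      score <- s_ins
      pos <- max(1L, i - 2L)
    } else if (s_del < score) {
      events[[length(events) + 1L]] <-
        .event_row(read_name, "deletion_filled", i, "", IUPAC_LETTERS[X])
      r <- cand_del
      score <- s_del
      pos <- max(1L, i - 1L)
    } else {
      pos <- i + 1L
    }
  }
  list(r = r, events = events)
}

# --- public API --------------------------------------------------------------

.bind_events <- function(evlist) {
  if (length(evlist) == 0L) .no_events() else do.call(rbind, evlist)
}

#' Correct homopolymer insertion errors in one read
#'
#' @param read DNA/IUPAC string.
#' @param consensus `consensus_ref` or IUPAC string.
#' @param read_name Name recorded in correction events.
#' @return List with `sequence` (corrected read) and `events` (data.frame of
#'   `read_name`, `kind`, `position`, `before`, `after`).
#' @export
fix_insertions <- function(read, consensus, read_name = "read") {
  consensus <- .as_consensus(consensus)
  res <- .pass_insertions(.encode_seq(read, "read"), .consensus_columns(consensus),
                          read_name, Inf)
  list(sequence = .decode_seq(res$r), events = .bind_events(res$events))
}

#' Correct homopolymer deletion errors in one read
#'
#' @inheritParams fix_insertions
#' @param max_length Bases shifted beyond this length are discarded.
#' @return As [fix_insertions()].
#' @export
fix_deletions <- function(read, consensus, read_name = "read", max_length = 300L) {
  consensus <- .as_consensus(consensus)
  res <- .pass_deletions(.encode_seq(read, "read"), .consensus_columns(consensus),
                         read_name, Inf, max_length)
  list(sequence = .decode_seq(res$r), events = .bind_events(res$events))
}

#' Correct compensated indels (insertion plus nearby deletion) in one read
#'
#' @inheritParams fix_deletions
#' @return As [fix_insertions()].
#' @export
fix_compensated_indels <- function(read, consensus, read_name = "read",
                                   max_length = 300L) {
  consensus <- .as_consensus(consensus)
  res <- .pass_compensated(.encode_seq(read, "read"), .consensus_columns(consensus),
                           read_name, Inf, max_length)
  list(sequence = .decode_seq(res$r), events = .bind_events(res$events))
}

#' Correct all homopolymer read errors in one read
#'
#' Scans mismatch positions 5' to 3', at each site competing the
#' insertion-removal repair against the deletion gap-fill repair and
#' applying whichever lowers the total mismatch count most; a
#' compensated-indel pass then handles paired indels, and the whole cycle
#' iterates to a fixpoint (or until `max_edits` accepted edits, in which
#' case the partially corrected read is emitted with `capped = TRUE`).
#' Deterministic for fixed input and parameters.
#'
#' @inheritParams fix_deletions
#' @param max_edits Cap on accepted edits per read (default 20).
#' @return List with `sequence`, `events`, and logical `capped`.
#' @examples
#' cons <- consensus_ref("ATTGCA")
#' correct_read("ATTTGCA", cons)$sequence  # "ATTGCA"
#' @export
correct_read <- function(read, consensus, read_name = "read",
                         max_length = 300L, max_edits = 20L) {
  consensus <- .as_consensus(consensus)
  cols <- .consensus_columns(consensus)
  r <- .encode_seq(read, "read")
  events <- list()
  capped <- FALSE
  repeat {
    n0 <- length(events)
    left <- function() max_edits - length(events)
    p1 <- .pass_sitewise(r, cols, read_name, left(), max_length)
    r <- p1$r; events <- c(events, p1$events)
    p2 <- .pass_compensated(r, cols, read_name, left(), max_length)
    r <- p2$r; events <- c(events, p2$events)
    if (length(events) >= max_edits) { capped <- TRUE; break }
    if (length(events) == n0) break
  }
  if (length(r) > max_length) r <- r[seq_len(max_length)]
  list(sequence = .decode_seq(r), events = .bind_events(events), capped = capped)
}

#' Correct a table of unique sequences and re-dereplicate
#'
#' Correction operates on unique sequences with their counts carried
#' through; corrected sequences that collide are merged and their counts
#' summed.
#'
#' @param uniques Unique-sequence data.frame.
#' @inheritParams correct_read
#' @return List with `uniques` (corrected, re-dereplicated), `events`
#'   (all correction events), and `capped` (names of reads that hit the
#'   edit cap).
#' @export
correct_uniques <- function(uniques, consensus, max_length = 300L, max_edits = 20L) {
  consensus <- .as_consensus(consensus)
  cols <- .consensus_columns(consensus)
  out <- character(nrow(uniques))
  events <- vector("list", nrow(uniques))
  capped <- logical(nrow(uniques))
  for (k in seq_len(nrow(uniques))) {
    res <- correct_read(uniques$sequence[k], consensus,
                        read_name = uniques$name[k],
                        max_length = max_length, max_edits = max_edits)
    out[k] <- res$sequence
    if (nrow(res$events)) events[[k]] <- res$events
    capped[k] <- res$capped
  }
  if (any(capped))
    warning(sprintf("%d read(s) hit the edit cap and were emitted in their current state",
                    sum(capped)))
  corrected <- uniques
  corrected$sequence <- out
  list(uniques = dereplicate(corrected),
       events = .bind_events(events[!vapply(events, is.null, TRUE)]),
       capped = uniques$name[capped])
}
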