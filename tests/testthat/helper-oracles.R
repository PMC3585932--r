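# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's internal encoding and matrices: IUPAC
# semantics are restated from the standard code table, and scores are
# recomputed by direct enumeration.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_match <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0L
}

# Naive double-loop suffix mismatch recount.
oracle_suffix_mm <- function(read, consensus, offset = 0L) {
  r <- strsplit(read, "")[[1]]
  k <- strsplit(consensus, "")[[1]]
  n <- length(r)
  m <- integer(n)
  for (i in seq_len(n)) {
    tot <- 0L
    for (j in i:n) if (!oracle_match(r[j], k[offset + j])) tot <- tot + 1L
    m[i] <- tot
  }
  m
}

# Plain (non-IUPAC) mismatch score of a candidate against a reference
# template; length differences are penalized one per overhanging base.
oracle_score <- function(cand, ref) {
  a <- strsplit(cand, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- min(length(a), length(b))
  sum(a[seq_len(n)] != b[seq_len(n)]) + abs(length(a) - length(b))
}

# Exhaustive single-indel repair: every single-base deletion and every
# single-base insertion (all four bases at all positions) is scored against
# the reference; the best-scoring repair is returned (ties: first found,
# scanning deletions 5'->3' then insertions 5'->3' by base). Scoring works
# on character vectors so the full enumeration stays fast.
oracle_single_indel_repair <- function(read, ref) {
  chars <- strsplit(read, "")[[1]]
  rchars <- strsplit(ref, "")[[1]]
  vscore <- function(a) {
    n <- min(length(a), length(rchars))
    sum(a[seq_len(n)] != rchars[seq_len(n)]) + abs(length(a) - length(rchars))
  }
  n <- length(chars)
  best_s <- vscore(chars)
  best_c <- chars
  for (p in seq_len(n)) {
    cand <- chars[-p]
    s <- vscore(cand)
    if (s < best_s) { best_s <- s; best_c <- cand }
  }
  for (p in seq_len(n + 1L)) {
    for (b in c("A", "C", "G", "T")) {
      cand <- append(chars, b, after = p - 1L)
      s <- vscore(cand)
      if (s < best_s) { best_s <- s; best_c <- cand }
    }
  }
  list(score = as.integer(best_s), repaired = paste(best_c, collapse = ""))
}

# Random IUPAC / DNA strings for property tests.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_iupac <- function(n) paste(sample(names(ORACLE_SETS), n, replace = TRUE),
                                  collapse = "")

# Inject exactly one homopolymer indel (insertion or deletion of one base
# of a run of >= 2) into a template, at a run ending at least `margin_3p`
# bases from the 3' end. Returns NULL when no eligible run exists.
inject_hp_indel <- function(template, margin_3p = 30L) {
  chars <- strsplit(template, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$lengths >= 2L & ends <= (length(chars) - margin_3p)
  if (!any(ok)) return(NULL)
  pick <- sample(which(ok), 1L)
  if (runif(1) < 0.5) {
    mutated <- append(chars, r$values[pick], after = starts[pick])
    kind <- "insertion"
  } else {
    mutated <- chars[-starts[pick]]
    kind <- "deletion"
  }
  list(read = paste(mutated, collapse = ""), kind = kind,
       run_start = starts[pick])
}

# Small unique-sequence table builder for filter tests.
utab <- function(...) {
  rows <- list(...)
  data.frame(name = vapply(rows, `[[`, "", 1L),
             count = as.integer(vapply(rows, function(r) r[[2L]], numeric(1))),
             sequence = vapply(rows, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "ampliclean")
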