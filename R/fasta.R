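# FASTA ingestion and output. Parsing is delegated to Biostrings; the
# wrappers add the error reporting and the ">name_count" header convention
# used for dereplicated sequences.

#' Read a FASTA file of reads
#'
#' @param path FASTA file (plain or gzip). Wrapped sequence lines are
#'   concatenated; record order is preserved.
#' @return A data.frame with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence` (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(.diagnose_fasta(path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop(sprintf("empty record '%s' (record %d) in %s", ids[bad], bad, path))
  }
  data.frame(id = unname(ids), sequence = unname(seqs), stringsAsFactors = FALSE)
}

# On a Biostrings parse failure, scan the raw lines to name the first
# structurally bad line (sequence before any header / empty record).
.diagnose_fasta <- function(path, msg) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (!is.null(lines)) {
    first_content <- which(nzchar(trimws(lines)))[1L]
    if (!is.na(first_content) && !startsWith(lines[first_content], ">"))
      return(sprintf("malformed FASTA %s: sequence before first header at line %d",
                     path, first_content))
    hdr <- startsWith(lines, ">")
    empty_rec <- which(hdr[-length(hdr)] & hdr[-1L])
    if (length(empty_rec))
      return(sprintf("malformed FASTA %s: empty record at line %d", path, empty_rec[1L]))
  }
  sprintf("malformed FASTA %s: %s", path, msg)
}

#' Write sequences to FASTA
#'
#' @param x Either a data.frame with `id`/`sequence` columns (reads) or a
#'   unique-sequence table with `name`/`count`/`sequence` columns, in which
#'   case headers are written as `name_count`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (all(c("name", "count") %in% names(x))) {
    headers <- paste0(x$name, "_", x$count)
  } else {
    headers <- x$id
  }
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file of dereplicated unique sequences
#'
#' Headers are expected in `name_count` form (e.g. `>Seq1_2343`); the
#' trailing `_count` token is parsed into the `count` column.
#'
#' @param path FASTA path.
#' @return Unique-sequence data.frame (`name`, `count`, `sequence`).
#' @export
read_uniques <- function(path) {
  reads <- read_fasta(path)
  m <- regmatches(reads$id, regexec("^(.*)_([0-9]+)$", reads$id))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop(sprintf("header '%s' lacks the trailing _count token", reads$id[!ok][1L]))
  data.frame(
    name = vapply(m, `[`, "", 2L),
    count = as.integer(vapply(m, `[`, "", 3L)),
    sequence = reads$sequence,
    stringsAsFactors = FALSE
  )
}

# Validated constructor for the unique-sequence table.
.uniques <- function(name, count, sequence) {
  stopifnot(length(name) == length(count), length(count) == length(sequence),
            all(count >= 1L))
  data.frame(name = name, count = as.integer(count), sequence = sequence,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Canonical ordering: descending count, ties by name.
.order_uniques <- function(u) {
  out <- u[order(-u$count, u$name), , drop = FALSE]
  row.names(out) <- NULL
  out
}
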