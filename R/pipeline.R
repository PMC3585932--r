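# Orchestration: full pipeline (steps 1-5 plus flagging) with per-step
# read accounting.

#' Pipeline configuration
#'
#' Defaults are the parameterization used for denoising COI test pools on a
#' 454 half-plate: minimum read length 170, truncation at 300, singleton
#' exclusion, 1 permitted mismatch to the consensus over the first 220
#' bases, and removal of sequences both <=1% divergent from and <10% as
#' frequent as a retained neighbour.
#'
#' @param primer Forward primer (IUPAC string), or `NULL` to skip trimming.
#' @param trim_length Primer bases to remove: `"full"` or an integer.
#' @param primer_max_mismatch Allowed primer mismatches (default 0).
#' @param min_length,max_length Read length filter/truncation (170/300).
#' @param min_count Minimum unique-sequence count kept at step 4 (default 2).
#' @param max_mismatch Permitted consensus mismatches at step 4 (default 1).
#' @param trim_to Alignment length retained at step 4 (default 220).
#' @param max_divergence Step-5 divergence threshold, fraction of length
#'   (default 0.01).
#' @param min_freq_ratio Step-5 frequency threshold (default 0.10).
#' @param consensus_offset Consensus position preceding read position 1
#'   (default 0).
#' @param max_edits Per-read correction edit cap (default 20).
#' @param min_state_freq Consensus builder state-frequency cutoff (default 0).
#' @param drop_flagged Remove flagged sequences instead of only reporting
#'   them (default FALSE; flags are advisory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(primer = NULL, trim_length = "full",
                            primer_max_mismatch = 0L,
                            min_length = 170L, max_length = 300L,
                            min_count = 2L, max_mismatch = 1L, trim_to = 220L,
                            max_divergence = 0.01, min_freq_ratio = 0.10,
                            consensus_offset = 0L, max_edits = 20L,
                            min_state_freq = 0, drop_flagged = FALSE) {
  cfg <- list(primer = primer, trim_length = trim_length,
              primer_max_mismatch = as.integer(primer_max_mismatch),
              min_length = as.integer(min_length),
              max_length = as.integer(max_length),
              min_count = as.integer(min_count),
              max_mismatch = as.integer(max_mismatch),
              trim_to = as.integer(trim_to),
              max_divergence = max_divergence,
              min_freq_ratio = min_freq_ratio,
              consensus_offset = as.integer(consensus_offset),
              max_edits = as.integer(max_edits),
              min_state_freq = min_state_freq,
              drop_flagged = isTRUE(drop_flagged))
  stopifnot(cfg$min_length <= cfg$max_length, cfg$min_count >= 1L,
            cfg$max_mismatch >= 0L, cfg$trim_to > 0L,
            cfg$max_divergence >= 0, cfg$max_divergence <= 1,
            cfg$min_freq_ratio > 0, cfg$min_freq_ratio <= 1)
  structure(cfg, class = "pipeline_config")
}

.accounting_row <- function(step, total, unique, total_base, unique_base) {
  data.frame(step = step, total_reads = total, unique_reads = unique,
             pct_total = round(100 * total / total_base, 1),
             pct_unique = round(100 * unique / unique_base, 1),
             stringsAsFactors = FALSE)
}

#' Run the full denoising pipeline
#'
#' Executes primer trimming, length filtering, dereplication (step 1),
#' homopolymer correction with re-dereplication (step 3), singleton
#' exclusion, consensus filtering, trimming and ambiguity-consistent
#' merging (step 4), the within-pool frequency filter (step 5), and
#' artifact flagging (step 6 support). Accounting percentages are computed
#' against the reads above the minimum length, separately for totals and
#' for unique sequences. Final sequences are renamed `Seq<rank>` by
#' descending count.
#'
#' @param reads Read data.frame (`id`, `sequence`) or a FASTA path.
#' @param consensus A `consensus_ref`, an IUPAC string, or a character
#'   vector/alignment of reference sequences from which to build one.
#' @param config A [pipeline_config()].
#' @return List with `uniques` (final sequences), `accounting` (per-step
#'   data.frame), `flags`, `removed` (step-5 removals), `events`
#'   (correction events), and `config`.
#' @export
run_pipeline <- function(reads, consensus, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_fasta(reads)
  if (nrow(reads) == 0L) stop("no input reads")

  if (inherits(consensus, "consensus_ref")) {
    # as given
  } else if (is.character(consensus) && length(consensus) > 1L) {
    consensus <- build_consensus(consensus, min_state_freq = config$min_state_freq,
                                 offset = config$consensus_offset)
  } else {
    consensus <- consensus_ref(consensus, offset = config$consensus_offset)
  }

  # --- step 1: trim, length-filter, dereplicate
  n_raw <- nrow(reads)
  if (!is.null(config$primer)) {
    tr <- trim_primer(reads, config$primer, trim_length = config$trim_length,
                      max_mismatch = config$primer_max_mismatch)
    reads <- tr$reads
  }
  fl <- filter_and_truncate(reads, config$min_length, config$max_length)
  reads <- fl$reads
  u1 <- dereplicate(reads)
  total_base <- nrow(reads)           # reads above minimum length
  unique_base <- nrow(u1)             # unique raw reads above minimum length
  if (total_base == 0L) stop("no reads above the minimum length")
  acct <- .accounting_row("step1_prep", total_base, nrow(u1), total_base, unique_base)

  # --- step 3: homopolymer correction, re-dereplication
  corr <- correct_uniques(u1, consensus, max_length = config$max_length,
                          max_edits = config$max_edits)
  u3 <- corr$uniques
  acct <- rbind(acct, .accounting_row("step3_correct", sum(u3$count), nrow(u3),
                                      total_base, unique_base))

  # --- step 4: singleton drop, consensus filter + trim, merge
  d4 <- drop_low_count(u3, config$min_count)
  f4 <- consensus_filter(d4$uniques, consensus,
                         max_mismatch = config$max_mismatch,
                         trim_to = config$trim_to)
  m4 <- merge_ambiguity_consistent(f4$uniques)
  u4 <- m4$uniques
  acct <- rbind(acct, .accounting_row("step4_reference_filter", sum(u4$count),
                                      nrow(u4), total_base, unique_base))

  # --- step 5: within-pool frequency filter
  f5 <- frequency_filter(u4, max_divergence = config$max_divergence,
                         min_freq_ratio = config$min_freq_ratio)
  u5 <- f5$retained
  acct <- rbind(acct, .accounting_row("step5_cluster_filter", sum(u5$count),
                                      nrow(u5), total_base, unique_base))

  # --- step 6 support: flagging (advisory unless drop_flagged)
  flags <- rbind(flag_compensated_indels(u5), flag_putative_numts(u5))
  if (config$drop_flagged && nrow(flags)) {
    u5 <- drop_flagged(u5, flags)
    acct <- rbind(acct, .accounting_row("step6_drop_flagged", sum(u5$count),
                                        nrow(u5), total_base, unique_base))
  }

  out <- .order_uniques(u5)
  if (nrow(out)) out$name <- sprintf("Seq%d", seq_len(nrow(out)))
  list(uniques = out, accounting = acct, flags = flags,
       removed = f5$removed, events = corr$events, config = config,
       consensus = consensus, n_raw = n_raw)
}

#' Write pipeline outputs to a directory
#'
#' Emits `cleaned.fasta` (headers `Seq<rank>_<count>`), `accounting.tsv`,
#' `flags.tsv`, `removed.tsv` and `events.tsv`.
#'
#' @param result List from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(result$uniques, file.path(dir, "cleaned.fasta"))
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(result$accounting, "accounting.tsv")
  tsv(result$flags, "flags.tsv")
  tsv(result$removed, "removed.tsv")
  tsv(result$events, "events.tsv")
  invisible(dir)
}
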