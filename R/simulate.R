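# Synthetic template communities and 454-like reads with homopolymer
# indels, point errors, and numts, plus a truth table, so every pipeline
# stage can be validated without external data.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a set of indel-free template sequences
#'
#' Templates emulate a community of haplotypes from a protein-coding
#' amplicon: equal length, no indels, and pairwise Hamming distances within
#' `[min_div, max_div]`. For wide divergence ranges the templates are drawn
#' from two clades separated by a deep split, mimicking a mix of inter- and
#' intraspecific variation; mutated position sets are disjoint so pairwise
#' distances are exact by construction and verified before returning.
#'
#' @param n Number of templates (default 27).
#' @param length Template length in nt (default 220).
#' @param min_div,max_div Bounds on pairwise Hamming distance (defaults 1
#'   and 60).
#' @param seed Integer seed; same seed, same templates.
#' @return Named character vector of template sequences (`T01`, `T02`, ...).
#' @export
simulate_templates <- function(n = 27L, length = 220L, min_div = 1L,
                               max_div = 60L, seed = NULL) {
  stopifnot(n >= 2L, min_div >= 1L, max_div >= min_div, max_div <= length)
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, length, replace = TRUE)
    k_lo <- max(1L, as.integer(ceiling(min_div / 2)))

    if (max_div >= 2L * k_lo) {
      split <- if (max_div >= 30L && n >= 6L) as.integer(floor(max_div * 2 / 3)) else 0L
      k_hi <- max(k_lo, min(as.integer(floor((max_div - split) / 2)),
                            as.integer(floor((length - split) / n))))
      k <- sample(seq.int(k_lo, k_hi), n, replace = TRUE)
      clade <- if (split > 0L) rep_len(c(1L, 2L), n) else rep(1L, n)
    } else if (n == 2L) {
      split <- 0L
      k <- c(0L, min_div)
      clade <- c(1L, 1L)
    } else {
      stop("infeasible divergence constraints for n > 2 templates")
    }
    if (split + sum(k) > length)
      stop("sequence length too short for the requested divergences")

    pos <- sample.int(length, split + sum(k))
    split_pos <- if (split > 0L) pos[seq_len(split)] else integer(0)
    rest <- if (split > 0L) pos[-seq_len(split)] else pos

    mutate <- function(chars, at) {
      for (p in at) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      chars
    }
    anc2 <- mutate(anc, split_pos)

    templates <- character(n)
    offset <- 0L
    for (i in seq_len(n)) {
      at <- if (k[i] > 0L) rest[(offset + 1L):(offset + k[i])] else integer(0)
      offset <- offset + k[i]
      start <- if (clade[i] == 1L) anc else anc2
      templates[i] <- paste(mutate(start, at), collapse = "")
    }
    names(templates) <- sprintf("T%02d", seq_len(n))

    d <- .pairwise_hamming(templates)
    dv <- d[upper.tri(d)]
    if (any(dv < min_div | dv > max_div))
      stop("internal error: simulated divergences outside the requested range")
    templates
  })
}

# Plain Hamming distance matrix for equal-length strings.
.pairwise_hamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' Error model for the read simulator
#'
#' @param hp_indel_rate Per-read probability that a homopolymer run of
#'   length 2 gains or loses one base; runs of length `len` use
#'   `hp_indel_rate * (len - 1)` (longer runs are noisier). Default 0.005.
#' @param point_error_rate Per-base substitution probability (default 0.001).
#' @param numt_per_template Numts injected per template (default 2).
#' @param numt_divergence Integer range of numt-to-parent mismatches
#'   (default `c(1, 2)`).
#' @param numt_rel_abundance Numt abundance relative to its parent template
#'   (default 0.05).
#' @return An `error_model` list.
#' @export
error_model <- function(hp_indel_rate = 0.005, point_error_rate = 0.001,
                        numt_per_template = 2L, numt_divergence = c(1L, 2L),
                        numt_rel_abundance = 0.05) {
  stopifnot(hp_indel_rate >= 0, hp_indel_rate <= 1,
            point_error_rate >= 0, point_error_rate <= 1,
            numt_per_template >= 0L, numt_rel_abundance >= 0,
            numt_rel_abundance <= 1)
  structure(list(hp_indel_rate = hp_indel_rate,
                 point_error_rate = point_error_rate,
                 numt_per_template = as.integer(numt_per_template),
                 numt_divergence = as.integer(range(numt_divergence)),
                 numt_rel_abundance = numt_rel_abundance),
            class = "error_model")
}

# Maximal homopolymer runs (length >= 2) in a character vector of bases.
.hp_runs <- function(chars) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= 2L
  data.frame(start = (ends - r$lengths + 1L)[keep], len = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Simulate demultiplexed 454-like reads from templates
#'
#' Each read is drawn from a template (or injected numt) according to its
#' abundance, then mutated: each homopolymer run may gain or lose one base
#' (insertion/deletion equally likely), and each base may be substituted.
#' Numts are extra low-abundance pool members differing from their parent
#' template at `numt_divergence` positions; they are subject to the same
#' read error process. Optionally a forward primer is prepended, with
#' degenerate positions resolved randomly per read.
#'
#' @param templates Named character vector from [simulate_templates()].
#' @param n_reads Number of reads to draw.
#' @param abundances Template abundances summing to 1 (default equal).
#' @param model An [error_model()].
#' @param primer Optional IUPAC primer string to prepend.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame `id`, `sequence`) and `truth`
#'   (list: `pool` data.frame of `name`, `sequence`, `abundance`, `type`,
#'   `parent`; `assignments` character vector mapping read id to pool
#'   member).
#' @export
simulate_reads <- function(templates, n_reads, abundances = NULL,
                           model = error_model(), primer = NULL, seed = NULL) {
  stopifnot(length(templates) >= 1L, n_reads >= 1L)
  if (is.null(abundances))
    abundances <- rep(1 / length(templates), length(templates))
  stopifnot(length(abundances) == length(templates),
            abs(sum(abundances) - 1) < 1e-8)

  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    pool <- data.frame(name = names(templates), sequence = unname(templates),
                       abundance = abundances, type = "template",
                       parent = NA_character_, stringsAsFactors = FALSE)
    # inject numts as extra low-abundance pool members
    if (model$numt_per_template > 0L && model$numt_rel_abundance > 0) {
      for (i in seq_along(templates)) {
        chars0 <- strsplit(templates[[i]], "", fixed = TRUE)[[1L]]
        for (j in seq_len(model$numt_per_template)) {
          d <- sample(seq.int(model$numt_divergence[1L], model$numt_divergence[2L]), 1L)
          at <- sample.int(length(chars0), d)
          chars <- chars0
          for (p in at) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
          pool <- rbind(pool, data.frame(
            name = sprintf("%s_numt%d", names(templates)[i], j),
            sequence = paste(chars, collapse = ""),
            abundance = abundances[i] * model$numt_rel_abundance,
            type = "numt", parent = names(templates)[i],
            stringsAsFactors = FALSE))
        }
      }
      pool$abundance <- pool$abundance / sum(pool$abundance)
    }

    chars_list <- strsplit(pool$sequence, "", fixed = TRUE)
    runs_list <- lapply(chars_list, .hp_runs)
    p_idx <- if (!is.null(primer)) .encode_seq(primer, what = "primer")

    pick <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = pool$abundance)
    seqs <- character(n_reads)
    for (k in seq_len(n_reads)) {
      m <- pick[k]
      chars <- chars_list[[m]]
      runs <- runs_list[[m]]
      out <- pool$sequence[m]
      edited <- FALSE
      if (nrow(runs) && model$hp_indel_rate > 0) {
        p_run <- pmin(1, model$hp_indel_rate * (runs$len - 1L))
        hit <- which(stats::runif(nrow(runs)) < p_run)
        if (length(hit)) {
          edited <- TRUE
          for (h in rev(hit)) {  # 3'->5' so positions stay valid
            if (stats::runif(1L) < 0.5) {
              chars <- append(chars, runs$base[h], after = runs$start[h])
            } else {
              chars <- chars[-runs$start[h]]
            }
          }
        }
      }
      if (model$point_error_rate > 0) {
        sub <- which(stats::runif(length(chars)) < model$point_error_rate)
        if (length(sub)) {
          edited <- TRUE
          for (p in sub) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        }
      }
      if (edited) out <- paste(chars, collapse = "")
      if (!is.null(p_idx)) {
        pchars <- vapply(p_idx, function(ix) {
          opts <- iupac_bases(IUPAC_LETTERS[ix])
          if (length(opts) == 1L) opts else sample(opts, 1L)
        }, "")
        out <- paste0(paste(pchars, collapse = ""), out)
      }
      seqs[k] <- out
    }
    ids <- sprintf("R%06d", seq_len(n_reads))
    list(reads = data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE),
         truth = list(pool = pool,
                      assignments = stats::setNames(pool$name[pick], ids)))
  })
}
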