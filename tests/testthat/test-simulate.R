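test_that("template simulation respects divergence bounds and the seed", {
  t1 <- simulate_templates(seed = 101)
  t2 <- simulate_templates(seed = 101)
  expect_identical(t1, t2)                      # determinism
  expect_identical(length(t1), 27L)
  expect_identical(unique(nchar(t1)), 220L)
  d <- outer(seq_along(t1), seq_along(t1), Vectorize(function(i, j) {
    sum(strsplit(t1[[i]], "")[[1]] != strsplit(t1[[j]], "")[[1]])
  }))
  dv <- d[upper.tri(d)]
  expect_identical(length(dv), 351L)            # all 27 choose 2 pairs
  expect_true(all(dv >= 1L & dv <= 60L))
  expect_false(identical(t1, simulate_templates(seed = 102)))
})

test_that("two templates at a fixed divergence differ at exactly that many sites", {
  t <- simulate_templates(n = 2, length = 100, min_div = 1, max_div = 1, seed = 5)
  d <- sum(strsplit(t[[1]], "")[[1]] != strsplit(t[[2]], "")[[1]])
  expect_identical(d, 1L)
})

test_that("zero error rates reproduce the templates verbatim", {
  tpl <- simulate_templates(n = 5, length = 120, seed = 9)
  sim <- simulate_reads(tpl, n_reads = 500,
                        model = error_model(hp_indel_rate = 0, point_error_rate = 0,
                                            numt_per_template = 0),
                        seed = 10)
  expect_identical(nrow(sim$reads), 500L)
  expect_true(all(sim$reads$sequence %in% tpl))
  expect_identical(unname(sim$truth$assignments),
                   names(tpl)[match(sim$reads$sequence, tpl)])
  # dereplication recovers exactly the sampled templates
  u <- dereplicate(sim$reads)
  expect_identical(sort(u$sequence), sort(unname(tpl[unique(sim$truth$assignments)])))
})

test_that("homopolymer-only errors differ from the template solely by run indels", {
  tpl <- simulate_templates(n = 2, length = 150, seed = 12)[1]
  sim <- simulate_reads(tpl, n_reads = 400,
                        model = error_model(hp_indel_rate = 0.1, point_error_rate = 0,
                                            numt_per_template = 0),
                        seed = 13)
  lens <- nchar(sim$reads$sequence)
  expect_true(any(lens != 150L))  # some indels occurred at this rate
  # indel-only error model: the optimal global alignment to the template
  # contains no substitutions, only gaps
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4)
  for (k in which(lens != 150L)[1:8]) {
    aln <- Biostrings::pairwiseAlignment(
      sim$reads$sequence[k], tpl[[1]], substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1, type = "global")
    expect_identical(Biostrings::nmismatch(aln), 0L)
  }
})

test_that("read counts per template follow the multinomial abundances", {
  tpl <- simulate_templates(n = 5, length = 100, seed = 21)
  ab <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  sim <- simulate_reads(tpl, n_reads = 10000, abundances = ab,
                        model = error_model(hp_indel_rate = 0, point_error_rate = 0,
                                            numt_per_template = 0),
                        seed = 22)
  counts <- table(factor(sim$truth$assignments, levels = names(tpl)))
  expect_gt(stats::chisq.test(counts, p = ab)$p.value, 0.001)
})

test_that("numts enter the pool at the configured relative abundance and distance", {
  tpl <- simulate_templates(n = 3, length = 200, seed = 31)
  model <- error_model(hp_indel_rate = 0, point_error_rate = 0,
                       numt_per_template = 2, numt_divergence = c(1, 2),
                       numt_rel_abundance = 0.05)
  sim <- simulate_reads(tpl, n_reads = 20000, model = model, seed = 32)
  pool <- sim$truth$pool
  numts <- pool[pool$type == "numt", ]
  expect_identical(nrow(numts), 6L)
  for (k in seq_len(nrow(numts))) {
    parent <- pool$sequence[pool$name == numts$parent[k]]
    d <- sum(strsplit(numts$sequence[k], "")[[1]] != strsplit(parent, "")[[1]])
    expect_true(d >= 1L && d <= 2L)
  }
  # realized numt read counts sit near 5% of the parent's (binomial sampling)
  counts <- table(sim$truth$assignments)
  for (k in seq_len(nrow(numts))) {
    nc <- counts[numts$name[k]]
    pc <- counts[numts$parent[k]]
    if (!is.na(nc) && !is.na(pc)) expect_lt(nc / pc, 0.15)
  }
})

test_that("an optional degenerate primer is prepended and trimmable", {
  tpl <- simulate_templates(n = 2, length = 100, seed = 41)
  primer <- "TTYCARAAYGG"
  sim <- simulate_reads(tpl, n_reads = 50,
                        model = error_model(hp_indel_rate = 0, point_error_rate = 0,
                                            numt_per_template = 0),
                        primer = primer, seed = 42)
  expect_true(all(nchar(sim$reads$sequence) == 100L + nchar(primer)))
  tr <- trim_primer(sim$reads, primer)
  expect_identical(tr$dropped, 0L)
  expect_true(all(tr$reads$sequence %in% tpl))
})
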