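test_that("insertion pass removes a homopolymer insertion", {
  res <- fix_insertions("ATTTGCA", "ATTGCA")
  expect_identical(res$sequence, "ATTGCA")
  expect_identical(res$events$kind, "insertion_removed")
  # identical read: untouched, no events
  res2 <- fix_insertions("ATTGCA", "ATTGCA")
  expect_identical(res2$sequence, "ATTGCA")
  expect_identical(nrow(res2$events), 0L)
  # mismatch without a preceding homopolymer is left alone by this pass
  res3 <- fix_insertions("ACTG", "ACCG")
  expect_identical(res3$sequence, "ACTG")
  expect_identical(nrow(res3$events), 0L)
})

test_that("deletion pass fills gaps by homopolymer extension or consensus symbol", {
  # extend the T homopolymer
  res <- fix_deletions("ATGCA", "ATTGCA")
  expect_identical(res$sequence, "ATTGCA")
  expect_identical(res$events$kind, "deletion_filled")
  expect_identical(res$events$after, "T")
  # no extendable homopolymer: consensus symbol written
  expect_identical(fix_deletions("AGCA", "ATGCA")$sequence, "ATGCA")
  # ambiguous consensus column, neither flank consistent: the code itself
  expect_identical(fix_deletions("TCAA", "TRCAA")$sequence, "TRCAA")
})

test_that("compensated-indel pass repairs paired indels and uses the tie rule", {
  res <- fix_compensated_indels("AAAGCTGCC", "AAGCTTGCC")
  expect_identical(res$sequence, "AAGCTTGCC")
  expect_identical(res$events$kind, "compensation")
  # substitution-only mismatch runs in a homopolymer-free template are not
  # "repaired": no run is available to delete from, and any gap insertion
  # misaligns the periodic suffix
  tpl <- strrep("ACGT", 15)
  mutated <- tpl
  substr(mutated, 21, 23) <- "CGA"  # three consecutive substitutions, no run created
  res2 <- fix_compensated_indels(mutated, tpl)
  expect_identical(res2$sequence, mutated)
  expect_identical(nrow(res2$events), 0L)
})

test_that("accepted edits never increase the total mismatch count", {
  set.seed(21)
  cons_seq <- random_dna(80)
  cons <- consensus_ref(cons_seq)
  for (rep in 1:100) {
    inj <- inject_hp_indel(cons_seq, margin_3p = 10L)
    if (is.null(inj)) next
    read <- inj$read
    res <- correct_read(read, cons, max_length = 120L)
    s_before <- oracle_score(read, cons_seq)
    s_after <- oracle_score(res$sequence, cons_seq)
    expect_lte(s_after, s_before)
  }
})

test_that("correct_read is idempotent and deterministic", {
  set.seed(33)
  cons_seq <- random_dna(100)
  cons <- consensus_ref(cons_seq)
  for (rep in 1:50) {
    inj <- inject_hp_indel(cons_seq, margin_3p = 10L)
    if (is.null(inj)) next
    r1 <- correct_read(inj$read, cons, max_length = 150L)
    r2 <- correct_read(r1$sequence, cons, max_length = 150L)
    expect_identical(r2$sequence, r1$sequence)
    expect_identical(nrow(r2$events), 0L)
    r3 <- correct_read(inj$read, cons, max_length = 150L)
    expect_identical(r3$sequence, r1$sequence)  # determinism
  }
})

test_that("corrected reads stay gap-free and within max_length", {
  set.seed(5)
  cons_seq <- random_dna(60)
  for (rep in 1:50) {
    read <- random_dna(sample(40:60, 1))
    res <- correct_read(read, cons_seq, max_length = 60L)
    expect_lte(nchar(res$sequence), 60L)
    expect_false(grepl("-", res$sequence, fixed = TRUE))
  }
})

test_that("single injected homopolymer indels away from the 3' end are restored", {
  set.seed(99)
  template <- simulate_templates(n = 2, length = 220, seed = 17)[[1]]
  cons <- consensus_ref(template)
  restored <- 0L
  n <- 200L
  for (rep in seq_len(n)) {
    inj <- inject_hp_indel(template, margin_3p = 30L)
    res <- correct_read(inj$read, cons)
    if (res$sequence == template) restored <- restored + 1L
    # repairs agree with the exhaustive single-indel oracle
    oracle <- oracle_single_indel_repair(inj$read, template)
    expect_identical(oracle$score, 0L)
    if (res$sequence == template)
      expect_identical(res$sequence, oracle$repaired)
  }
  expect_gte(restored / n, 0.99)
})

test_that("the edit cap limits corrections and flags the read", {
  template <- strrep("AACCGGTT", 5)
  chars <- strsplit(template, "")[[1]]
  for (p in c(33L, 25L, 17L, 9L, 1L)) chars <- append(chars, chars[p], after = p)
  read <- paste(chars, collapse = "")  # five homopolymer insertions
  full <- correct_read(read, template, max_length = 45L)
  expect_identical(full$sequence, template)
  expect_false(full$capped)
  capped <- correct_read(read, template, max_length = 45L, max_edits = 3L)
  expect_true(capped$capped)
  expect_lte(nrow(capped$events), 3L)
  expect_false(identical(capped$sequence, template))
})

test_that("correcting unique tables carries counts and re-merges collisions", {
  template <- "AATTGGCCAATTGGCC"
  cons <- consensus_ref(template)
  u <- utab(list("u1", 5, template),
            list("u2", 3, "AATTTGGCCAATTGGCC"),   # extra T -> corrects to template
            list("u3", 2, "AATTGGCCAATTGGC"))     # lost final C (3' end)
  res <- correct_uniques(u, cons, max_length = 16L)
  expect_identical(sum(res$uniques$count), 10L)
  top <- res$uniques[res$uniques$sequence == template, ]
  expect_gte(top$count, 8L)  # u2 collapses into u1
})
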