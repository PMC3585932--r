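mk220 <- function(base, at = integer(0), to = "A") {
  s <- strsplit(base, "")[[1]]
  for (p in at) s[p] <- to
  paste(s, collapse = "")
}

test_that("frequency filter removes rare near-identical sequences", {
  set.seed(4)
  base <- random_dna(220)
  u <- utab(list("major", 1000, base),
            list("rare_close", 50, mk220(base, 7, "A")),     # 1 mm, 5%
            list("abundant_close", 200, mk220(base, 13, "A")), # 1 mm, 20%
            list("rare_far", 30, mk220(base, c(30, 60, 90), "A"))) # 3 mm
  # ensure the intended distances (substitution target may equal original)
  u$sequence[2] <- mk220(base, 7, setdiff(c("A", "C"), substr(base, 7, 7))[1])
  u$sequence[3] <- mk220(base, 13, setdiff(c("A", "C"), substr(base, 13, 13))[1])
  for (p in c(30, 60, 90)) {
    cur <- substr(u$sequence[4], p, p)
    substr(u$sequence[4], p, p) <- setdiff(c("A", "C"), cur)[1]
  }
  res <- frequency_filter(u, max_divergence = 0.01, min_freq_ratio = 0.10)
  expect_setequal(res$retained$name, c("major", "abundant_close", "rare_far"))
  expect_identical(res$removed$name, "rare_close")
  expect_identical(res$removed$neighbor, "major")
  expect_identical(res$removed$distance, 1L)
})

test_that("the global most-frequent sequence is always retained", {
  set.seed(14)
  for (rep in 1:20) {
    base <- random_dna(50)
    u <- utab()
    for (k in 1:10) {
      s <- strsplit(base, "")[[1]]
      at <- sample(50, sample(0:2, 1))
      for (p in at) s[p] <- sample(c("A", "C", "G", "T"), 1)
      u <- rbind(u, utab(list(sprintf("s%02d", k), sample(1:500, 1),
                              paste(s, collapse = ""))))
    }
    u <- u[!duplicated(u$sequence), ]
    res <- frequency_filter(u, max_divergence = 0.05, min_freq_ratio = 0.2)
    top <- u$name[order(-u$count, u$name)][1]
    expect_true(top %in% res$retained$name)
    # count conservation across the split
    expect_identical(sum(res$retained$count) + sum(res$removed$count),
                     sum(u$count))
  }
})

test_that("frequency filter output is invariant to input order", {
  set.seed(6)
  base <- random_dna(100)
  u <- utab()
  for (k in 1:15) {
    s <- strsplit(base, "")[[1]]
    at <- sample(100, sample(0:3, 1))
    for (p in at) s[p] <- sample(c("A", "C", "G", "T"), 1)
    u <- rbind(u, utab(list(sprintf("s%02d", k), sample(1:300, 1),
                            paste(s, collapse = ""))))
  }
  u <- u[!duplicated(u$sequence), ]
  ref <- frequency_filter(u)
  for (rep in 1:5) {
    perm <- u[sample(nrow(u)), ]
    res <- frequency_filter(perm)
    expect_identical(res$retained, ref$retained)
  }
})

test_that("retention is monotone in both thresholds", {
  set.seed(8)
  base <- random_dna(100)
  u <- utab()
  for (k in 1:20) {
    s <- strsplit(base, "")[[1]]
    at <- sample(100, sample(0:4, 1))
    for (p in at) s[p] <- sample(c("A", "C", "G", "T"), 1)
    u <- rbind(u, utab(list(sprintf("s%02d", k), sample(1:300, 1),
                            paste(s, collapse = ""))))
  }
  u <- u[!duplicated(u$sequence), ]
  # growing min_freq_ratio can only shrink the retained set
  prev <- NULL
  for (r in c(0.05, 0.10, 0.25, 0.50)) {
    kept <- frequency_filter(u, max_divergence = 0.03, min_freq_ratio = r)$retained$name
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # growing max_divergence can only shrink the retained set
  prev <- NULL
  for (d in c(0.00, 0.01, 0.03, 0.08)) {
    kept <- frequency_filter(u, max_divergence = d, min_freq_ratio = 0.2)$retained$name
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("divergence threshold uses floor(fraction * length)", {
  base <- strrep("ACGT", 55)  # 220 nt
  two <- base; three <- base
  substr(two, 1, 1) <- "T"; substr(two, 5, 5) <- "T"
  substr(three, 1, 1) <- "T"; substr(three, 5, 5) <- "T"; substr(three, 9, 9) <- "T"
  u <- utab(list("major", 1000, base), list("d2", 20, two), list("d3", 20, three))
  res <- frequency_filter(u, max_divergence = 0.01, min_freq_ratio = 0.10)
  # floor(0.01 * 220) = 2: the 2-mismatch rare sequence goes, 3-mismatch stays
  expect_setequal(res$retained$name, c("major", "d3"))
})

test_that("unequal lengths are rejected", {
  expect_error(frequency_filter(utab(list("a", 2, "AAAA"), list("b", 1, "AAA"))),
               "equal-length")
})
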