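test_that("planted exact duplicates and palindromes are found", {
  set.seed(61)
  ch <- strsplit(rand_dna(1000L), "")[[1L]]
  ch[201:240] <- ch[601:640]                    # 40 bp forward duplicate
  s <- paste(ch, collapse = "")
  hits <- find_repeats(s, repeat_params(30L, 0L, "F"))
  oracle <- oracle_find_repeats(s, 30L, 0L, "F")
  expect_identical(hits, oracle)
  expect_true(any(hits$start1 == 200L & hits$start2 == 600L &
                  hits$length >= 40L & hits$mismatches == 0L))

  ch2 <- strsplit(rand_dna(800L), "")[[1L]]
  seg <- ch2[101:135]
  ch2[501:535] <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[seg]))
  s2 <- paste(ch2, collapse = "")
  hits2 <- find_repeats(s2, repeat_params(30L, 0L, "P"))
  expect_true(any(hits2$type == "P" & hits2$start1 == 100L &
                  hits2$start2 == 500L & hits2$length >= 35L))
})

test_that("finder matches the exhaustive window oracle for every type and k", {
  set.seed(67)
  for (rep in 1:2) {
    s <- rand_dna(250L, at = 0.6)
    for (k in 0:3) {
      hits <- find_repeats(s, repeat_params(12L, k))
      oracle <- oracle_find_repeats(s, 12L, k)
      expect_identical(hits, oracle, label = paste("rep", rep, "k", k))
    }
  }
})

test_that("every hit at k extends to a hit at k + 1", {
  set.seed(71)
  s <- rand_dna(300L, at = 0.65)
  for (k in 0:2) {
    h0 <- find_repeats(s, repeat_params(12L, k))
    h1 <- find_repeats(s, repeat_params(12L, k + 1L))
    for (i in seq_len(nrow(h0))) {
      a1 <- h0$start1[i]; b1 <- h0$end1[i]
      a2 <- h0$start2[i]; b2 <- h0$end2[i]
      same <- h1$type == h0$type[i]
      covered <- any(same &
        ((h1$start1 <= a1 & h1$end1 >= b1 &
          h1$start2 <= a2 & h1$end2 >= b2) |
         (h1$start1 <= a2 & h1$end1 >= b2 &
          h1$start2 <= a1 & h1$end2 >= b1)))
      expect_true(covered, label = paste("hit", i, "at k", k))
    }
  }
})

test_that("palindrome detection is invariant under reverse complement", {
  set.seed(73)
  for (i in 1:3) {
    s <- rand_dna(300L)
    h1 <- find_repeats(s, repeat_params(12L, 1L, "P"))
    h2 <- find_repeats(revcomp(s), repeat_params(12L, 1L, "P"))
    expect_identical(nrow(h1), nrow(h2))
    expect_identical(sort(h1$length), sort(h2$length))
    expect_identical(sort(h1$mismatches), sort(h2$mismatches))
  }
})

test_that("planted repeats appear at their mismatch budget and not below", {
  b <- simulate_plastome(sim_config(seed = 81L))
  tr <- b$repeat_truth
  p_row <- tr[tr$type == "P" & tr$mismatches == 2L, ]
  at2 <- find_repeats(b$ancestor, repeat_params(30L, 2L, "P"))
  expect_true(any(at2$start1 == p_row$start1 & at2$start2 == p_row$start2 &
                  at2$length == p_row$length & at2$mismatches == 2L))
  at1 <- find_repeats(b$ancestor, repeat_params(30L, 1L, "P"))
  covering <- at1$start1 <= p_row$start1 & at1$end1 >= p_row$end1
  expect_false(any(covering))
})

test_that("the genome's own IR pair is excluded from summaries", {
  b <- simulate_plastome(bare_sim_config(83L))
  hits <- find_repeats(b$ancestor, repeat_params(30L, 0L, "P"))
  ir_hit <- hits$start1 == b$partition$ira[1L] &
            hits$start2 == b$partition$irb[1L] &
            hits$length == 600L
  expect_true(any(ir_hit))
  kept <- exclude_ir_mirror(hits, b$partition)
  expect_false(any(kept$start1 == b$partition$ira[1L] &
                   kept$length == 600L))
})

test_that("repeat loci collapse by type, length and region", {
  part <- structure(list(lsc = c(0L, 1000L), ira = c(1000L, 1200L),
                         ssc = c(1200L, 1500L), irb = c(1500L, 1700L),
                         genome_length = 1700L), class = "region_partition")
  hits <- data.frame(
    type = c("F", "F", "F"),
    start1 = c(10L, 100L, 300L), end1 = c(52L, 142L, 343L),
    start2 = c(500L, 600L, 700L), end2 = c(542L, 642L, 743L),
    length = c(42L, 42L, 43L), mismatches = 0L, stringsAsFactors = FALSE)
  loci <- collapse_loci(hits, part)
  expect_identical(nrow(loci), 2L)
  l42 <- loci[loci$length == 42L, ]
  expect_identical(l42$members, 2L)
  expect_identical(l42$regions, "LSC+LSC")
})

test_that("histogram bins follow the 30/40/50/60 length classes", {
  hits <- data.frame(type = c("F", "P", "R", "F"),
                     length = c(30L, 45L, 60L, 39L))
  h <- repeat_histogram(hits)
  total <- h[h$type == "total", ]
  expect_identical(total$`30-39`, 2L)
  expect_identical(total$`40-49`, 1L)
  expect_identical(total$`50-59`, 0L)
  expect_identical(total$`>=60`, 1L)
  expect_identical(h[h$type == "R", ]$`>=60`, 1L)
})

test_that("repeat parameters are validated", {
  expect_error(repeat_params(min_len = 7L), "min_len")
  expect_error(find_repeats("AC-GT", repeat_params(8L, 0L)), "gap")
})
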