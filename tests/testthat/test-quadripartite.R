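test_that("a planted quadripartite structure is recovered exactly", {
  b <- simulate_plastome(bare_sim_config(101L))
  res <- suppressWarnings(detect_quadripartite(b$ancestor, min_ir_len = 300L))
  expect_identical(res$partition$lsc, c(0L, 2000L))
  expect_identical(res$partition$ira, c(2000L, 2600L))
  expect_identical(res$partition$ssc, c(2600L, 3400L))
  expect_identical(res$partition$irb, c(3400L, 4000L))
  p <- res$partition
  s <- res$record$seq
  ira <- substr(s, p$ira[1L] + 1L, p$ira[2L])
  irb <- substr(s, p$irb[1L] + 1L, p$irb[2L])
  expect_identical(ira, revcomp(irb))
  # partition covers the genome without gaps
  expect_identical(p$lsc[2L], p$ira[1L])
  expect_identical(p$ira[2L], p$ssc[1L])
  expect_identical(p$ssc[2L], p$irb[1L])
  expect_identical(p$irb[2L], p$genome_length)
})

test_that("detection is rotation-invariant and canonicalization idempotent", {
  b <- simulate_plastome(bare_sim_config(202L))
  res0 <- suppressWarnings(detect_quadripartite(b$ancestor, 300L))
  n <- nchar(b$ancestor$seq)
  for (off in c(137L, 1500L, 3990L)) {
    rot <- seq_record("rot", plastidkit:::rotate_seq(b$ancestor$seq, off),
                      circular = TRUE)
    res <- suppressWarnings(detect_quadripartite(rot, 300L))
    expect_identical(res$record$seq, res0$record$seq)
    expect_identical(res$partition, res0$partition)
  }
  # idempotence: detecting on the canonical genome is the identity
  res1 <- suppressWarnings(detect_quadripartite(res0$record, 300L))
  expect_identical(res1$partition, res0$partition)
  expect_false(res1$transform$flipped)
  expect_identical(res1$transform$shift, 0L)
  # strand-flip invariance: the reverse complement canonicalizes identically
  flip <- seq_record("flip", revcomp(b$ancestor$seq), circular = TRUE)
  resf <- suppressWarnings(detect_quadripartite(flip, 300L))
  expect_identical(resf$record$seq, res0$record$seq)
})

test_that("a genome with no long inverted repeat is rejected", {
  set.seed(5)
  rec <- seq_record("r", rand_dna(4000L), circular = TRUE)
  expect_error(suppressWarnings(detect_quadripartite(rec, 500L)), "no IR")
  lin <- seq_record("l", rand_dna(4000L), circular = FALSE)
  expect_error(detect_quadripartite(lin), "not circular")
})

test_that("A+T content follows its definition", {
  expect_identical(at_content(seq_record("a", "ATAT")), 1)
  expect_identical(at_content(seq_record("b", "ACGT")), 0.5)
  expect_identical(at_content(seq_record("c", "ANTN")), 1)  # N excluded
  expect_error(at_content(seq_record("d", "NNNN")), "all N")
})

test_that("junction table reports planted bp splits and overlaps", {
  b <- simulate_plastome(sim_config(seed = 33L))
  jt <- junction_table(b$partition, b$features)
  rps19 <- jt[jt$gene == "rps19", ]
  expect_identical(rps19$junction, "LSC/IRa")
  expect_identical(rps19$bp_left, 100L)
  expect_identical(rps19$bp_right, 179L)
  # gene extending 17 bp past the IRa/SSC border
  ycf1f <- jt[jt$gene == "ycf1f", ]
  expect_identical(ycf1f$bp_right, 17L)
  # 25 bp overlap between the two genes crossing IRa/SSC
  expect_identical(ycf1f$overlap_partner, "ndhF")
  expect_identical(ycf1f$overlap_bp, 25L)
  ycf1 <- jt[jt$gene == "ycf1", ]
  expect_identical(ycf1$junction, "SSC/IRb")
  expect_identical(c(ycf1$bp_left, ycf1$bp_right), c(1100L, 500L))
  # the IRb/LSC junction is intergenic, with flanking genes named
  origin <- jt[jt$junction == "IRb/LSC", ]
  expect_identical(origin$gene, "intergenic")
  expect_identical(origin$overlap_partner, "rrn16b-trnH")
})

test_that("an empty feature list yields four intergenic junction records", {
  b <- simulate_plastome(bare_sim_config(7L))
  jt <- junction_table(b$partition, list())
  expect_identical(nrow(jt), 4L)
  expect_true(all(jt$gene == "intergenic"))
})

test_that("region_of classifies containment and boundary crossing", {
  b <- simulate_plastome(bare_sim_config(8L))
  p <- b$partition
  expect_identical(region_of(p, 10L, 50L), "LSC")
  expect_identical(region_of(p, 2100L, 2150L), "IRa")
  expect_identical(region_of(p, 1990L, 2010L), "junction-spanning")
  expect_identical(region_of(p, 3500L, 3600L), "IRb")
})
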