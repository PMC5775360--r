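test_that("threshold semantics: (A)10 is reported, (A)9 is not", {
  left <- "GACTGGTCAGCTTGCAGTAC"; right <- "GTCACCGATGGTATCGGCAT"
  s10 <- paste0(left, strrep("A", 10), right)
  hits <- find_ssrs(s10)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif, "A")
  expect_identical(hits$units, 10L)
  expect_identical(hits$start, 20L)
  s9 <- paste0(left, strrep("A", 9), right)
  expect_identical(nrow(find_ssrs(s9)), 0L)
  expect_error(find_ssrs("AC-GT"), "gap")
})

test_that("tracts are reported at their minimal period only", {
  s <- paste0("CCG", strrep("AT", 5), "GCC")
  hits <- find_ssrs(s)
  expect_identical(hits$motif, "AT")
  expect_identical(hits$period, 2L)
  expect_identical(hits$units, 5L)
  # divisor re-check on random scans
  set.seed(41)
  for (i in 1:5) {
    hits <- find_ssrs(rand_dna(3000L, at = 0.7))
    if (!nrow(hits)) next
    for (j in seq_len(nrow(hits))) {
      expect_true(plastidkit:::motif_is_primitive(hits$motif[j]))
      expect_identical(hits$tract_length[j], hits$period[j] * hits$units[j])
    }
  }
})

test_that("scanner matches the exhaustive regex oracle on seeded sequences", {
  set.seed(17)
  for (at in c(0.5, 0.75)) {
    for (rep in 1:3) {
      s <- rand_dna(1500L, at = at)
      expect_identical(find_ssrs(s), oracle_find_ssrs(s), label = paste(at, rep))
    }
  }
})

test_that("per-period hit counts are strand-symmetric", {
  set.seed(23)
  for (i in 1:5) {
    s <- rand_dna(4000L, at = 0.72)
    h1 <- find_ssrs(s)
    h2 <- find_ssrs(revcomp(s))
    expect_identical(table(factor(h1$period, levels = 1:6)),
                     table(factor(h2$period, levels = 1:6)))
  }
})

test_that("hit counts never increase when thresholds rise", {
  set.seed(29)
  s <- rand_dna(5000L, at = 0.72)
  base <- nrow(find_ssrs(s))
  for (p in 1:6) {
    mu <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
    mu[p] <- mu[p] + 2L
    expect_lte(nrow(find_ssrs(s, ssr_params(mu))), base)
  }
})

test_that("region and genomic context match the generator truth", {
  b <- simulate_plastome(sim_config(seed = 55L))
  hits <- contextualize_ssrs(find_ssrs(b$ancestor), b$features, b$partition)
  truth <- b$ssr_truth
  m <- merge(truth, hits, by = "start", suffixes = c(".t", ".h"))
  expect_identical(nrow(m), nrow(truth))  # every planted SSR found
  expect_identical(m$region.h, m$region.t)
  expect_identical(m$context.h, m$context.t)
  cds <- m[m$context.t == "CDS", ]
  expect_identical(cds$gene.h, cds$gene.t)
})

test_that("SSR loci merge across species and flag polymorphism", {
  aln <- alignment_matrix(
    c("a", "b", "c"),
    c("CCAAAAAAAAAAGG--TT",   # (A)10
      "CCAAAAAAAAAAGGCCTT",   # (A)10 identical
      "AAAAAAAAAACCGGCCTT"))  # (A)10 shifted to overlap partially
  hits <- lapply(c(a = "a", b = "b", c = "c"), function(id) {
    row <- paste(aln$mat[id, ][aln$mat[id, ] != "-"], collapse = "")
    find_ssrs(row)
  })
  loci <- ssr_loci(aln, hits)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_species_present, 3L)
  expect_false(loci$polymorphic)  # all descriptors Ax10

  # different unit counts at the same locus are polymorphic
  aln2 <- alignment_matrix(
    c("a", "b"),
    c("CCAAAAAAAAAA--GG",
      "CCAAAAAAAAAAAAGG"))
  hits2 <- list(a = find_ssrs("CCAAAAAAAAAAGG"),
                b = find_ssrs("CCAAAAAAAAAAAAGG"))
  loci2 <- ssr_loci(aln2, hits2)
  expect_identical(nrow(loci2), 1L)
  expect_true(loci2$polymorphic)

  # a species with no overlapping hit is recorded absent (and polymorphic)
  aln3 <- alignment_matrix(
    c("a", "b"),
    c("CCAAAAAAAAAAGG",
      "CCAAAAACAAAAGG"))
  hits3 <- list(a = find_ssrs("CCAAAAAAAAAAGG"),
                b = find_ssrs("CCAAAAACAAAAGG"))
  loci3 <- ssr_loci(aln3, hits3)
  expect_identical(nrow(loci3), 1L)
  expect_true(grepl("b:absent", loci3$descriptors))
  expect_true(loci3$polymorphic)

  expect_error(ssr_loci(aln3, list(zz = hits3$a)), "not in alignment")
})

test_that("planted loci and polymorphism counts equal generator truth", {
  # evolve a small bundle, then force known unit-count mutations
  b <- simulate_dataset(small_sim_config(91L))
  hits <- lapply(b$species, find_ssrs)
  loci <- ssr_loci(b$alignment, hits)
  # every planted SSR column interval appears among the loci
  map <- which(b$alignment$mat[1L, ] != "-") - 1L
  for (i in seq_len(nrow(b$ssr_truth))) {
    cs <- map[b$ssr_truth$start[i] + 1L]
    hit <- any(loci$col_start <= cs & loci$col_end > cs)
    expect_true(hit, label = paste("locus at", cs))
  }
})

test_that("per-genome summaries count by period, context and region", {
  b <- simulate_plastome(sim_config(seed = 77L))
  hits <- contextualize_ssrs(find_ssrs(b$ancestor), b$features, b$partition)
  sm <- ssr_summary(hits, "anc")
  expect_identical(sm$total, nrow(hits))
  expect_identical(sm$mono + sm$di + sm$tri + sm$tetra + sm$penta + sm$hexa,
                   sm$total)
  expect_identical(sm$IGS + sm$intron + sm$CDS, sm$total)
  # planted layout: one IRa SSR mirrored into IRb
  expect_gte(sm$IR, 2L)
  empty <- ssr_summary(find_ssrs("GACTGGTCAGCTTGCAGTAC"), "none")
  expect_identical(empty$total, 0L)
  expect_identical(empty$mono, 0L)
})
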