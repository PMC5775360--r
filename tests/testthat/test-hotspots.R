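test_that("window placement follows start/step arithmetic with truncation", {
  aln <- alignment_matrix(c("a", "b"), c(strrep("A", 1000L), strrep("A", 1000L)))
  w <- window_scan(aln)
  expect_identical(w$start, c(0L, 200L, 400L, 600L, 800L))
  expect_identical(w$end, c(600L, 800L, 1000L, 1000L, 1000L))
  expect_identical(w$truncated, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(w$S == 0L))
  expect_true(all(w$pi == 0))
  short <- alignment_matrix(c("a", "b"), c(strrep("A", 150L), strrep("A", 150L)))
  expect_warning(ws <- window_scan(short), "shorter than window length")
  expect_identical(nrow(ws), 1L)
})

test_that("the mean + k*sd rule is exact on hand-computed window lists", {
  mk <- function(svals) {
    data.frame(start = seq.int(0L, by = 200L, length.out = length(svals)),
               end = seq.int(600L, by = 200L, length.out = length(svals)),
               S = svals)
  }
  # all-equal S: sd = 0, strict inequality selects nothing
  expect_identical(nrow(select_hotspots(mk(rep(5L, 10L)))), 0L)
  # [1,1,1,1,20]: T = 4.8 + 2*7.6 = 20.0 (population sd); 20 > 20 fails
  expect_identical(nrow(select_hotspots(mk(c(1L, 1L, 1L, 1L, 20L)))), 0L)
  # sample-sd convention agrees here: T = 4.8 + 2*8.497 = 21.79
  expect_identical(
    nrow(select_hotspots(mk(c(1L, 1L, 1L, 1L, 20L)),
                         window_params(sd_type = "sample"))), 0L)
  # a window strictly above threshold is selected and overlapping
  # neighbours merge into one interval
  sv <- c(2L, 2L, 30L, 30L, rep(2L, 16L))
  thr <- mean(sv) + 2 * sqrt(mean((sv - mean(sv))^2))
  expect_true(all(sv[3:4] > thr) && all(sv[-(3:4)] <= thr))
  sel <- select_hotspots(mk(sv))
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$start, 400L)
  expect_identical(sel$end, 1200L)
  expect_identical(sel$n_windows, 2L)
  # windows separated by a gap stay separate intervals
  wide <- data.frame(start = c(0L, 100L, 5000L),
                     end = c(600L, 700L, 5600L),
                     S = c(50L, 50L, 50L))
  wide <- rbind(wide, data.frame(start = seq(10000L, by = 200L, length.out = 20L),
                                 end = seq(10600L, by = 200L, length.out = 20L),
                                 S = 0L))
  sel2 <- select_hotspots(wide)
  expect_identical(nrow(sel2), 2L)
  expect_error(select_hotspots(mk(3L)), "sd undefined")
})

test_that("raising k_sd never adds a selected window", {
  set.seed(131)
  svals <- rpois(40L, 8L) + c(rep(0L, 35L), rep(40L, 5L))
  w <- data.frame(start = seq.int(0L, by = 200L, length.out = 40L),
                  end = seq.int(600L, by = 200L, length.out = 40L),
                  S = svals)
  prev <- Inf
  for (k in c(0.5, 1, 2, 3, 5)) {
    n_sel <- sum(select_hotspots(w, window_params(k_sd = k))$n_windows)
    expect_lte(n_sel, prev)
    prev <- n_sel
  }
})

test_that("hotspot naming uses containing genes, flanks, and a/b suffixes", {
  feats <- list(gene_feature("trnK", "tRNA", 100L, 180L),
                gene_feature("rps16", "CDS", 900L, 1200L),
                gene_feature("ycf1", "CDS", 2000L, 4000L))
  seqs <- strrep("A", 4500L)
  aln <- alignment_matrix(c("r", "s"), c(seqs, seqs))
  iv <- data.frame(start = c(300L, 2100L, 3200L),
                   end = c(800L, 2700L, 3800L), n_windows = 1L)
  hot <- annotate_hotspots(iv, aln, feats, "r")
  expect_identical(hot$name, c("trnK-rps16", "ycf1a", "ycf1b"))
  expect_error(annotate_hotspots(iv, aln, feats, "zz"), "not in alignment")
  # an interval overlapping a gene joins flanks and overlapped genes
  iv2 <- data.frame(start = c(700L), end = c(1500L), n_windows = 1L)
  hot2 <- annotate_hotspots(iv2, aln, feats, "r")
  expect_identical(hot2$name, "trnK-rps16-ycf1")
})

test_that("planted high-rate intervals are recovered as hotspot regions", {
  b <- simulate_dataset(sim_config(seed = 211L))
  w <- window_scan(b$alignment)
  # the highest-diversity window overlaps a planted interval
  top <- w[which.max(w$pi), ]
  planted <- b$hotspot_truth
  expect_true(any(top$start < planted$end & top$end > planted$start))
  sel <- select_hotspots(w)
  expect_identical(nrow(sel), nrow(planted))
  for (i in seq_len(nrow(planted))) {
    expect_true(any(sel$start < planted$end[i] & sel$end > planted$start[i]),
                label = paste("planted hotspot", i))
  }
  hot <- annotate_hotspots(sel, b$alignment, b$features, "t1")
  expect_true("ycf1" %in% hot$name)  # the SSC hotspot sits inside ycf1
  expect_true(all(hot$S >= hot$PI))
})
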