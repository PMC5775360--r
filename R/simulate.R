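# Seeded synthetic-plastome generator. Builds a circular quadripartite
# ancestor (LSC + IRa + SSC + IRb, IRb = reverse complement of IRa) with
# planted junction-spanning genes, perfect SSRs, and large repeats at known
# coordinates, then evolves species along a known tree under a Jukes-Cantor
# substitution model (substitution-only, so the true alignment is the
# identity mapping). Rate multipliers create divergence hotspots; IRa
# mutations are mirrored into IRb so the two IR copies evolve in concert.

#' Simulation configuration
#'
#' Defaults define a 20 kb toy plastome (LSC 11 kb, IR 3.5 kb, SSC 2 kb) at
#' ~63% A+T with a gene layout that reproduces the qualitative junction
#' biology of plastomes (a gene crossing LSC/IRa, two overlapping genes at
#' IRa/SSC, a large gene crossing SSC/IRb), one planted perfect SSR of each
#' motif period 1-5 (plus an intronic and an IR-resident one), one planted
#' repeat of each type F/R/C/P at >= 30 bp, eight taxa related by a balanced
#' two-clade tree with 0.01 expected substitutions/site per branch, and
#' three 800 bp hotspot intervals at 10x the background rate.
#'
#' @param seed Integer seed; same seed gives a bit-identical bundle.
#' @param lsc_len,ir_len,ssc_len Region lengths in bp.
#' @param at Target A+T fraction of the background sequence.
#' @param genes List of `gene_feature` (canonical coordinates).
#' @param ssrs Data.frame of planted SSRs: `motif`, `units`, `pos`, plus
#'   expected `region`, `context`, `gene`.
#' @param repeats Data.frame of planted repeats: `type`, `length`,
#'   `mismatches`, `pos1`, `pos2`.
#' @param tree Newick string with branch lengths in expected
#'   substitutions/site.
#' @param hotspots Data.frame of hotspot intervals: `start`, `end` (0-based
#'   half-open, in LSC/SSC only).
#' @param hotspot_multiplier Rate multiplier inside hotspot intervals.
#' @param ir_damp Rate multiplier for IRa sites (IRs are the most conserved
#'   part of real plastomes).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       lsc_len = 11000L, ir_len = 3500L, ssc_len = 2000L,
                       at = 0.63,
                       genes = default_gene_layout(),
                       ssrs = default_ssr_layout(),
                       repeats = default_repeat_layout(),
                       tree = default_tree(),
                       hotspots = default_hotspot_layout(),
                       hotspot_multiplier = 10,
                       ir_damp = 0.2) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len > 0L, lsc_len >= ssc_len,
            hotspot_multiplier >= 1)
  cfg <- structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                        ir_len = as.integer(ir_len),
                        ssc_len = as.integer(ssc_len), at = at, genes = genes,
                        ssrs = ssrs, repeats = repeats, tree = tree,
                        hotspots = hotspots,
                        hotspot_multiplier = hotspot_multiplier,
                        ir_damp = ir_damp), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  planted_end <- cfg$lsc_len + cfg$ir_len + cfg$ssc_len
  iv <- list()
  if (nrow(cfg$ssrs)) {
    for (i in seq_len(nrow(cfg$ssrs))) {
      len <- nchar(cfg$ssrs$motif[i]) * cfg$ssrs$units[i]
      iv[[length(iv) + 1L]] <- c(cfg$ssrs$pos[i], cfg$ssrs$pos[i] + len)
    }
  }
  if (nrow(cfg$repeats)) {
    for (i in seq_len(nrow(cfg$repeats))) {
      L <- cfg$repeats$length[i]
      iv[[length(iv) + 1L]] <- c(cfg$repeats$pos1[i], cfg$repeats$pos1[i] + L)
      iv[[length(iv) + 1L]] <- c(cfg$repeats$pos2[i], cfg$repeats$pos2[i] + L)
    }
  }
  if (length(iv)) {
    m <- do.call(rbind, iv)
    if (any(m[, 1L] < 1L) || any(m[, 2L] > planted_end - 1L)) {
      stop("planted element outside the LSC+IRa+SSC span", call. = FALSE)
    }
    ord <- order(m[, 1L])
    m <- m[ord, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L] + 2L)) {
      stop("planted elements overlap (or lack a 1 bp flank buffer)",
           call. = FALSE)
    }
  }
  if (nrow(cfg$hotspots)) {
    total <- cfg$lsc_len + 2L * cfg$ir_len + cfg$ssc_len
    ira <- c(cfg$lsc_len, cfg$lsc_len + cfg$ir_len)
    irb <- c(total - cfg$ir_len, total)
    for (i in seq_len(nrow(cfg$hotspots))) {
      h <- c(cfg$hotspots$start[i], cfg$hotspots$end[i])
      if (h[2L] <= h[1L] || h[2L] > total) stop("bad hotspot interval", call. = FALSE)
      if ((h[1L] < ira[2L] && h[2L] > ira[1L]) ||
          (h[1L] < irb[2L] && h[2L] > irb[1L])) {
        stop("hotspot intervals must lie in single-copy regions", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_gene_layout <- function() {
  g <- function(name, kind, s, e, strand = "+") {
    gene_feature(name, kind, s, e, strand)
  }
  list(
    g("trnH", "tRNA", 30L, 110L),
    g("psbA", "CDS", 150L, 550L),
    g("trnK", "tRNA", 1500L, 1580L),
    g("matK", "CDS", 1700L, 2300L),
    gene_feature("rps16", "CDS", c(2500L, 2800L), c(2600L, 2900L)),
    g("psbM", "CDS", 3500L, 3700L),
    g("trnD", "tRNA", 4400L, 4480L),
    g("rps4", "CDS", 5000L, 5600L),
    g("trnT", "tRNA", 5900L, 5980L),
    g("trnL", "tRNA", 6300L, 6380L),
    g("ycf4", "CDS", 7000L, 7550L),
    g("cemA", "CDS", 7900L, 8500L),
    g("petA", "CDS", 8800L, 9700L),
    g("psbJ", "CDS", 9900L, 10020L),
    g("rps19", "CDS", 10900L, 11179L),          # crosses LSC/IRa (100|179)
    g("rrn16", "rRNA", 11800L, 12300L),
    g("ycf1f", "CDS", 12800L, 14517L),          # crosses IRa/SSC (1700|17)
    g("ndhF", "CDS", 14492L, 15092L, "-"),      # crosses IRa/SSC, 25 bp overlap
    g("rpl32", "CDS", 15150L, 15280L),
    g("ycf1", "CDS", 15400L, 17000L),           # crosses SSC/IRb (1100|500)
    g("rrn16b", "rRNA", 18700L, 19200L, "-")    # IRb mirror of rrn16
  )
}

#' @rdname sim_config
#' @export
default_ssr_layout <- function() {
  data.frame(
    motif = c("A", "AT", "AAT", "AT", "AAG", "AATC", "AACCT", "T"),
    units = c(12L, 7L, 4L, 6L, 5L, 4L, 3L, 11L),
    pos = c(600L, 1000L, 1850L, 2650L, 3050L, 4700L, 6500L, 11300L),
    region = c(rep("LSC", 7L), "IRa"),
    context = c("IGS", "IGS", "CDS", "intron", "IGS", "IGS", "IGS", "IGS"),
    gene = c("", "", "matK", "rps16", "", "", "", ""),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_repeat_layout <- function() {
  data.frame(type = c("F", "P", "R", "C"),
             length = c(40L, 45L, 36L, 33L),
             mismatches = c(0L, 2L, 0L, 1L),
             pos1 = c(700L, 2350L, 4900L, 5700L),
             pos2 = c(8200L, 9600L, 10100L, 10300L),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_hotspot_layout <- function() {
  data.frame(start = c(3850L, 8700L, 15500L),
             end = c(4650L, 9500L, 16300L))
}

#' @rdname sim_config
#' @export
default_tree <- function() {
  paste0("(((t1:0.01,t2:0.01):0.01,(t3:0.01,t4:0.01):0.01):0.01,",
         "((t5:0.01,t6:0.01):0.01,(t7:0.01,t8:0.01):0.01):0.01);")
}

random_dna <- function(n, at = 0.63) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

# pick a base different from each element of `avoid` (vector of base sets)
base_not <- function(...) {
  avoid <- unique(unlist(list(...)))
  setdiff(DNA_BASES, avoid)[1L]
}

#' Simulate a synthetic plastome ancestor
#'
#' Builds the ancestor sequence `LSC + IRa + SSC + revcomp(IRa)` with all
#' planted elements at recorded coordinates. Flanking bases around planted
#' SSRs and repeats are adjusted so each planted element is exactly maximal
#' at its recorded extent, and the bases flanking the IR copies are adjusted
#' so the planted IR is exactly the maximal inverted repeat.
#'
#' @param config A [sim_config()] object.
#' @return A truth bundle: `ancestor` (`seq_record`), `features`,
#'   `partition`, `ssr_truth`, `repeat_truth`, `hotspot_truth`, `tree`
#'   (a `phylo`), and `config`.
#' @export
simulate_plastome <- function(config) {
  set.seed(config$seed)
  L <- config$lsc_len; I <- config$ir_len; S <- config$ssc_len
  n <- L + 2L * I + S
  core <- random_dna(L + I + S, config$at)   # LSC + IRa + SSC
  core <- plant_ssrs(core, config$ssrs)
  core <- plant_repeats(core, config$repeats)
  ch <- c(core, rev(complement_chars(core[(L + 1L):(L + I)])))
  # break IR extension at the four region borders:
  # left of IRa (pos L) pairs with right of IRb (pos 1, circular)
  if (ch[L] == complement_chars(ch[1L])) {
    ch[1L] <- base_not(complement_chars(ch[L]))
  }
  # right of IRa (first SSC base) pairs with left of IRb (last SSC base)
  if (ch[L + I + 1L] == complement_chars(ch[L + I + S])) {
    ch[L + I + S] <- base_not(complement_chars(ch[L + I + 1L]))
  }
  partition <- structure(list(lsc = c(0L, L), ira = c(L, L + I),
                              ssc = c(L + I, L + I + S), irb = c(L + I + S, n),
                              genome_length = n), class = "region_partition")
  ssr_truth <- ssr_truth_table(config, partition)
  list(ancestor = seq_record("ancestor", chars_seq(ch), circular = TRUE),
       features = config$genes, partition = partition,
       ssr_truth = ssr_truth,
       repeat_truth = repeat_truth_table(config),
       hotspot_truth = config$hotspots,
       tree = ape::read.tree(text = config$tree),
       config = config)
}

plant_ssrs <- function(ch, ssrs) {
  if (!nrow(ssrs)) return(ch)
  for (i in seq_len(nrow(ssrs))) {
    motif <- seq_chars(ssrs$motif[i])
    p <- length(motif); u <- ssrs$units[i]; a <- ssrs$pos[i]  # 0-based
    tract <- rep(motif, u)
    ch[(a + 1L):(a + p * u)] <- tract
    # break tandem extension: left flank vs motif's last base, right flank
    # vs motif's first base (period-p run conditions)
    if (ch[a] == motif[p]) ch[a] <- base_not(motif[p])
    if (ch[a + p * u + 1L] == motif[1L]) ch[a + p * u + 1L] <- base_not(motif[1L])
  }
  ch
}

plant_repeats <- function(ch, repeats) {
  if (!nrow(repeats)) return(ch)
  for (i in seq_len(nrow(repeats))) {
    ty <- repeats$type[i]; L <- repeats$length[i]; m <- repeats$mismatches[i]
    a <- repeats$pos1[i]; b <- repeats$pos2[i]  # 0-based starts
    src <- ch[(a + 1L):(a + L)]
    copy2 <- switch(ty, F = src, R = rev(src),
                    C = complement_chars(src),
                    P = rev(complement_chars(src)))
    if (m > 0L) {
      at <- round(seq_len(m) * L / (m + 1L))
      for (x in at) copy2[x] <- base_not(copy2[x])
    }
    ch[(b + 1L):(b + L)] <- copy2
    # break extension on both sides under the type's transform
    flank <- switch(ty,
      F = list(c(a, b), c(a + L + 1L, b + L + 1L)),
      C = list(c(a, b), c(a + L + 1L, b + L + 1L)),
      R = list(c(a, b + L + 1L), c(a + L + 1L, b)),
      P = list(c(a, b + L + 1L), c(a + L + 1L, b)))
    for (fp in flank) {
      x <- fp[1L]; y <- fp[2L]
      matches <- if (ty %in% c("C", "P")) {
        ch[x] == complement_chars(ch[y])
      } else ch[x] == ch[y]
      if (matches) {
        ch[y] <- if (ty %in% c("C", "P")) base_not(complement_chars(ch[x]))
                 else base_not(ch[x])
      }
    }
  }
  ch
}

ssr_truth_table <- function(config, partition) {
  ssrs <- config$ssrs
  if (!nrow(ssrs)) {
    return(data.frame(motif = character(), period = integer(),
                      units = integer(), start = integer(), end = integer(),
                      region = character(), context = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  per <- nchar(ssrs$motif)
  truth <- data.frame(motif = ssrs$motif, period = per, units = ssrs$units,
                      start = ssrs$pos, end = ssrs$pos + per * ssrs$units,
                      region = ssrs$region, context = ssrs$context,
                      gene = ssrs$gene, stringsAsFactors = FALSE)
  # each IRa-resident SSR has a mirrored reverse-complement copy in IRb
  in_ira <- truth$region == "IRa"
  if (any(in_ira)) {
    mir <- truth[in_ira, , drop = FALSE]
    ira_end <- partition$ira[2L]; irb_start <- partition$irb[1L]
    new_start <- irb_start + (ira_end - mir$end)
    mir_motif <- vapply(mir$motif, revcomp, "")
    mir$start <- new_start; mir$end <- new_start + mir$period * mir$units
    mir$motif <- mirror_motif_phase(mir_motif)
    mir$region <- "IRb"
    truth <- rbind(truth, mir)
  }
  truth[order(truth$start), , drop = FALSE]
}

# the scanner reports the leftmost phase of a tandem run; for a mirrored
# tract the observed motif is the reverse complement rotated to phase 0,
# which for whole-unit tracts is just the reverse complement
mirror_motif_phase <- function(motifs) motifs

repeat_truth_table <- function(config) {
  r <- config$repeats
  if (!nrow(r)) {
    return(data.frame(type = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(), end2 = integer(),
                      length = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(type = r$type, start1 = r$pos1, end1 = r$pos1 + r$length,
             start2 = r$pos2, end2 = r$pos2 + r$length, length = r$length,
             mismatches = r$mismatches, stringsAsFactors = FALSE)
}

#' Evolve species from a simulated ancestor along the configured tree
#'
#' Substitution-only Jukes-Cantor evolution: along a branch of length `t`
#' (expected substitutions/site) each site changes to a given other base
#' with probability `(1 - exp(-4 t m / 3)) / 4`, where `m` is the site's
#' rate multiplier (`hotspot_multiplier` inside hotspot intervals, `ir_damp`
#' in IRa, 1 elsewhere). Mutations are applied to LSC, IRa and SSC; IRb is
#' then rewritten as the reverse complement of IRa, so the IR copies evolve
#' in concert and `IRa == revcomp(IRb)` holds in every species. Because no
#' indels are introduced, the true alignment is the stacked species
#' sequences.
#'
#' @param bundle Truth bundle from [simulate_plastome()].
#' @param config The same [sim_config()] (defaults to `bundle$config`).
#' @return The bundle extended with `species` (list of `seq_record`) and
#'   `alignment` (the true `alignment_matrix`).
#' @export
evolve_plastome <- function(bundle, config = bundle$config) {
  set.seed(derive_seed(config$seed, 1000003L))
  tree <- bundle$tree
  part <- bundle$partition
  n <- part$genome_length
  mult <- rep(1, n)
  if (nrow(config$hotspots)) {
    for (i in seq_len(nrow(config$hotspots))) {
      mult[(config$hotspots$start[i] + 1L):config$hotspots$end[i]] <-
        config$hotspot_multiplier
    }
  }
  ira_idx <- (part$ira[1L] + 1L):part$ira[2L]
  mult[ira_idx] <- config$ir_damp
  active <- seq_len(part$ssc[2L])  # LSC + IRa + SSC
  mult_active <- mult[active]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- seq_chars(bundle$ancestor$seq)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1L]; child <- edges$edge[e, 2L]
    t_br <- edges$edge.length[e]
    ch <- seqs[[parent]]
    ch[active] <- jc_mutate(ch[active], t_br, mult_active)
    ch[(part$irb[1L] + 1L):part$irb[2L]] <-
      rev(complement_chars(ch[ira_idx]))
    seqs[[child]] <- ch
  }
  species <- lapply(seq_len(ntip), function(i) {
    seq_record(tree$tip.label[i], chars_seq(seqs[[i]]), circular = TRUE)
  })
  names(species) <- tree$tip.label
  aln <- alignment_matrix(tree$tip.label,
                          vapply(species, `[[`, "", "seq"))
  bundle$species <- species
  bundle$alignment <- aln
  bundle
}

jc_mutate <- function(ch, t_br, mult) {
  if (t_br <= 0) return(ch)
  p_change <- 0.75 * (1 - exp(-4 * t_br * mult / 3))
  hit <- which(stats::runif(length(ch)) < p_change)
  if (!length(hit)) return(ch)
  cur <- match(ch[hit], DNA_BASES)
  off <- sample.int(3L, length(hit), replace = TRUE)
  ch[hit] <- DNA_BASES[((cur - 1L + off) %% 4L) + 1L]
  ch
}

#' Simulate a complete dataset (ancestor plus evolved species)
#'
#' @param config A [sim_config()] object.
#' @return The full truth bundle (see [simulate_plastome()] and
#'   [evolve_plastome()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  simulate_plastome(config) |> evolve_plastome(config)
}
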