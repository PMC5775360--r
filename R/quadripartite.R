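# Quadripartite structure detection. The IR pair is located as the longest
# pair of disjoint maximal exact inverted repeats on the circular sequence
# (seed k-mers shared between the doubled genome and its reverse complement,
# extended along diagonals; maximal = extension stops at the first mismatch).

#' Detect the LSC/IRa/SSC/IRb partition of a circular plastome
#'
#' Finds the longest pair of disjoint maximal exact inverted repeats (the IR),
#' then rotates (and possibly strand-flips) the genome so that the region
#' order is LSC, IRa, SSC, IRb starting with LSC at base 1. The large
#' single-copy region is the longer of the two arcs between the IR copies.
#' Strand is chosen so that, when annotations are supplied, the majority of
#' LSC CDS bases lie on the forward strand; without annotations the
#' orientation with the lexicographically smaller LSC sequence is used.
#'
#' @param record A circular `seq_record`.
#' @param min_ir_len Minimum IR length in bp (default 1000).
#' @param features Optional feature list (on the input coordinates) used only
#'   to orient the strand; remap them afterwards with [transform_features()].
#' @return A list with `record` (canonicalized), `partition` (a
#'   `region_partition`: 0-based half-open `lsc`, `ira`, `ssc`, `irb`,
#'   `genome_length`), and `transform` (`flipped`, `shift`; see
#'   [transform_features()]).
#' @export
detect_quadripartite <- function(record, min_ir_len = 1000L, features = NULL) {
  stopifnot(inherits(record, "seq_record"))
  if (!record$circular) stop("record is not circular", call. = FALSE)
  n <- nchar(record$seq)
  if (n < 10000L) {
    warning("genome shorter than 10 kb (", n, " bp); quadripartite detection ",
            "may be unreliable", call. = FALSE)
  }
  pair <- find_longest_ir_pair(record$seq, min_ir_len)
  build_canonical(record, pair, features)
}

# longest disjoint maximal exact inverted-repeat pair on a circular sequence;
# returns list(a, b, len) with 0-based starts mod n
find_longest_ir_pair <- function(s, min_ir_len) {
  n <- nchar(s)
  if (min_ir_len >= n) stop("no IR found (min_ir_len >= genome length)", call. = FALSE)
  s2 <- paste0(s, s)
  m <- 2L * n
  k <- min(20L, as.integer(min_ir_len))
  cs2 <- seq_chars(s2)
  cr <- rev(complement_chars(cs2))
  r <- chars_seq(cr)
  np <- m - k + 1L
  km_s <- substring(s2, 1:np, k:m)
  km_r <- substring(r, 1:np, k:m)
  shared <- intersect(unique(km_s), unique(km_r))
  if (!length(shared)) stop("no IR found (>= ", min_ir_len, " bp)", call. = FALSE)
  pos_s <- split(seq_len(np), factor(km_s, levels = shared))
  pos_r <- split(seq_len(np), factor(km_r, levels = shared))
  diags <- unique(unlist(lapply(shared, function(w) {
    as.vector(outer(pos_r[[w]], pos_s[[w]], `-`))
  }), use.names = FALSE))
  cand <- list()
  for (d in diags) {
    i0 <- max(1L, 1L - d); i1 <- min(m, m - d)
    if (i1 - i0 + 1L < min_ir_len) next
    eq <- cs2[i0:i1] == cr[(i0:i1) + d]
    runs <- true_runs(eq)
    runs <- runs[(runs$end - runs$start) >= min_ir_len, , drop = FALSE]
    for (ri in seq_len(nrow(runs))) {
      L <- runs$end[ri] - runs$start[ri]
      if (L > n) next  # periodic artifact of doubling
      a1 <- i0 + runs$start[ri]              # 1-based start on s2, copy A
      b1end <- a1 + d + L - 1L               # 1-based end in r-space
      c1 <- m + 1L - b1end                   # 1-based start on s2, copy B
      a0 <- (a1 - 1L) %% n
      c0 <- (c1 - 1L) %% n
      if (!circ_disjoint(a0, c0, L, n)) next
      key <- paste(min(a0, c0), max(a0, c0), L)
      cand[[key]] <- list(a = min(a0, c0), b = max(a0, c0), len = L)
    }
  }
  if (!length(cand)) stop("no IR found (>= ", min_ir_len, " bp)", call. = FALSE)
  lens <- vapply(cand, `[[`, 0L, "len")
  best <- cand[lens == max(lens)]
  if (length(best) > 1L) {
    # tie-break: minimize |LSC - SSC| arc difference, then lowest start
    score <- vapply(best, function(p) {
      g1 <- (p$b - (p$a + p$len)) %% n
      g2 <- (p$a - (p$b + p$len)) %% n
      abs(g1 - g2)
    }, 0L)
    best <- best[score == min(score)]
    if (length(best) > 1L) {
      starts <- vapply(best, `[[`, 0L, "a")
      best <- best[starts == min(starts)]
    }
    if (length(best) > 1L) stop("ambiguous IR pair (unresolvable tie)", call. = FALSE)
  }
  best[[1L]]
}

# are circular intervals [a, a+L) and [b, b+L) mod n disjoint?
circ_disjoint <- function(a, b, L, n) {
  if (2L * L > n) return(FALSE)
  gap1 <- (b - (a + L)) %% n
  gap2 <- (a - (b + L)) %% n
  gap1 + gap2 + 2L * L == n
}

rotate_seq <- function(s, offset) {
  n <- nchar(s)
  offset <- offset %% n
  if (offset == 0L) return(s)
  paste0(substr(s, offset + 1L, n), substr(s, 1L, offset))
}

build_canonical <- function(record, pair, features) {
  s <- record$seq
  n <- nchar(s)
  L <- pair$len
  arc1_start <- (pair$a + L) %% n; arc1_len <- (pair$b - arc1_start) %% n
  arc2_start <- (pair$b + L) %% n; arc2_len <- (pair$a - arc2_start) %% n
  if (arc1_len >= arc2_len) {
    lsc_start <- arc1_start; lsc_len <- arc1_len
    ira_start <- pair$b; ssc_len <- arc2_len
  } else {
    lsc_start <- arc2_start; lsc_len <- arc2_len
    ira_start <- pair$a; ssc_len <- arc1_len
  }
  fwd <- list(flipped = FALSE, shift = lsc_start)
  # flipped candidate: reverse complement maps position p to n-1-p; the LSC
  # interval maps onto itself reversed, so the flipped LSC start is n - lsc_end
  lsc_end <- (lsc_start + lsc_len) %% n
  flp <- list(flipped = TRUE, shift = (n - lsc_end) %% n)
  part <- function() {
    structure(list(lsc = c(0L, lsc_len),
                   ira = c(lsc_len, lsc_len + L),
                   ssc = c(lsc_len + L, lsc_len + L + ssc_len),
                   irb = c(lsc_len + L + ssc_len, n),
                   genome_length = n), class = "region_partition")
  }
  seq_fwd <- rotate_seq(s, fwd$shift)
  seq_flp <- rotate_seq(revcomp(s), flp$shift)
  choose_flip <- FALSE
  if (!is.null(features) && length(features)) {
    cds_fwd <- lsc_forward_cds_bp(features, fwd, n, lsc_len)
    cds_flp <- lsc_forward_cds_bp(features, flp, n, lsc_len)
    if (cds_flp > cds_fwd) choose_flip <- TRUE
  } else {
    lsc_fwd <- substr(seq_fwd, 1L, lsc_len)
    lsc_flp <- substr(seq_flp, 1L, lsc_len)
    if (lsc_flp < lsc_fwd) choose_flip <- TRUE
  }
  tr <- if (choose_flip) flp else fwd
  canon <- seq_record(record$id, if (choose_flip) seq_flp else seq_fwd,
                      circular = TRUE)
  list(record = canon, partition = part(), transform = tr)
}

lsc_forward_cds_bp <- function(features, transform, n, lsc_len) {
  mapped <- transform_features(features, transform, n)
  total <- 0L
  for (f in mapped) {
    if (f$kind != "CDS") next
    for (i in seq_len(nrow(f$parts))) {
      if (f$parts$strand[i] != "+") next
      lo <- max(f$parts$start[i], 0L); hi <- min(f$parts$end[i], lsc_len)
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total
}

#' Remap features through a canonicalization transform
#'
#' Applies the rotation/strand-flip returned by [detect_quadripartite()] to a
#' feature list. Intervals that would straddle the new origin are represented
#' unwrapped (end may exceed the genome length).
#'
#' @param features List of `gene_feature` objects on the original coordinates.
#' @param transform The `transform` element returned by [detect_quadripartite()].
#' @param genome_length Genome length in bp.
#' @return Remapped feature list.
#' @export
transform_features <- function(features, transform, genome_length) {
  n <- genome_length
  lapply(features, function(f) {
    p <- f$parts
    if (transform$flipped) {
      new_start <- n - p$end
      new_end <- n - p$start
      p$start <- new_start; p$end <- new_end
      p$strand <- ifelse(p$strand == "+", "-", "+")
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    p$start <- (p$start - transform$shift) %% n
    p$end <- p$start + (f$parts$end - f$parts$start)[
      if (transform$flipped) rev(seq_len(nrow(f$parts))) else seq_len(nrow(f$parts))]
    rownames(p) <- NULL
    gene_feature(f$name, f$kind, p$start, p$end, p$strand)
  })
}

#' A+T content of a sequence
#'
#' @param record A `seq_record` (or plain character scalar).
#' @return `(A + T) / (non-N bases)` as a fraction in `[0, 1]`.
#' @export
at_content <- function(record) {
  s <- if (inherits(record, "seq_record")) record$seq else record
  ch <- seq_chars(s)
  nonN <- sum(ch != "N")
  if (nonN == 0L) stop("A+T content undefined: sequence is all N", call. = FALSE)
  sum(ch == "A" | ch == "T") / nonN
}

#' Region label of an interval under a partition
#'
#' @param partition A `region_partition`.
#' @param start,end 0-based half-open interval.
#' @return One of `"LSC"`, `"IRa"`, `"SSC"`, `"IRb"`, or
#'   `"junction-spanning"` when the interval crosses a region boundary.
#' @export
region_of <- function(partition, start, end) {
  for (nm in c("lsc", "ira", "ssc", "irb")) {
    iv <- partition[[nm]]
    if (start >= iv[1L] && end <= iv[2L]) {
      return(c(lsc = "LSC", ira = "IRa", ssc = "SSC", irb = "IRb")[[nm]])
    }
  }
  "junction-spanning"
}

junction_positions <- function(partition) {
  c("LSC/IRa" = partition$lsc[2L], "IRa/SSC" = partition$ira[2L],
    "SSC/IRb" = partition$ssc[2L], "IRb/LSC" = partition$irb[2L])
}

#' Junction gene table
#'
#' For each of the four region junctions, reports every gene whose span
#' crosses it, with the bp of the gene falling on each side, and any overlap
#' with another junction-crossing gene. A junction crossed by no gene yields
#' one `intergenic` record whose `overlap_partner` names the flanking genes
#' (joined by `-`) and whose `bp_left`/`bp_right` give the intergenic gap on
#' each side of the junction.
#'
#' @param partition A `region_partition` on canonical coordinates.
#' @param features Feature list on canonical coordinates (spans crossing the
#'   origin unwrapped, i.e. `end` may exceed the genome length).
#' @return A data.frame with columns `junction`, `gene`, `bp_left`,
#'   `bp_right`, `overlap_partner`, `overlap_bp`.
#' @export
junction_table <- function(partition, features) {
  n <- partition$genome_length
  jpos <- junction_positions(partition)
  spans <- if (length(features)) {
    data.frame(gene = vapply(features, `[[`, "", "name"),
               start = vapply(features, function(f) min(f$parts$start), 0L),
               end = vapply(features, function(f) max(f$parts$end), 0L))
  } else data.frame(gene = character(), start = integer(), end = integer())
  rows <- list()
  for (jn in names(jpos)) {
    b <- jpos[[jn]]
    crossing <- which(spans$start < b & spans$end > b)
    if (b == n) {  # origin junction: also genes unwrapped past the origin
      crossing <- which(spans$start < b & spans$end > b)
    }
    if (length(crossing)) {
      for (gi in crossing) {
        partners <- setdiff(crossing, gi)
        op <- NA_character_; ob <- NA_integer_
        if (length(partners)) {
          ovl <- pmin(spans$end[partners], spans$end[gi]) -
                 pmax(spans$start[partners], spans$start[gi])
          keep <- which(ovl > 0L)
          if (length(keep)) {
            j <- partners[keep[which.max(ovl[keep])]]
            op <- spans$gene[j]; ob <- max(ovl[keep])
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, gene = spans$gene[gi],
          bp_left = b - spans$start[gi], bp_right = spans$end[gi] - b,
          overlap_partner = op, overlap_bp = ob)
      }
    } else {
      left <- right <- NA_character_
      bp_l <- bp_r <- NA_integer_
      if (nrow(spans)) {
        dl <- (b - spans$end) %% n
        dr <- (spans$start - b) %% n
        left <- spans$gene[which.min(dl)]; bp_l <- min(dl)
        right <- spans$gene[which.min(dr)]; bp_r <- min(dr)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene = "intergenic", bp_left = bp_l, bp_right = bp_r,
        overlap_partner = if (is.na(left)) NA_character_
                          else paste0(left, "-", right),
        overlap_bp = NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition as a BED data.frame
#'
#' @param partition A `region_partition`.
#' @param genome_id Sequence id for the first BED column.
#' @return A data.frame with BED columns (0-based half-open).
#' @export
partition_bed <- function(partition, genome_id = "genome") {
  data.frame(chrom = genome_id,
             start = c(partition$lsc[1L], partition$ira[1L],
                       partition$ssc[1L], partition$irb[1L]),
             end = c(partition$lsc[2L], partition$ira[2L],
                     partition$ssc[2L], partition$irb[2L]),
             name = c("LSC", "IRa", "SSC", "IRb"))
}
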