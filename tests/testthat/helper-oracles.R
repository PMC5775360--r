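# Independent brute-force oracles used to verify the package's scanners and
# statistics. These deliberately use different algorithms from the package
# (regex scans, exhaustive window enumeration, explicit state enumeration).

oracle_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

oracle_comp <- function(ch) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
}

# all primitive motifs of a given period
oracle_primitive_motifs <- function(p) {
  motifs <- apply(do.call(expand.grid,
                          rep(list(c("A", "C", "G", "T")), p)),
                  1L, paste, collapse = "")
  keep <- vapply(motifs, function(m) {
    for (q in seq_len(p - 1L)) {
      if (p %% q == 0L && identical(strrep(substr(m, 1L, q), p / q), m)) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  motifs[keep]
}

# regex-based SSR oracle: greedy whole-unit matches per primitive motif,
# then left-to-right consumption per period (a hit must start at or after
# the previous reported hit's end)
oracle_find_ssrs <- function(s, min_units = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  out <- list()
  for (p in 1:6) {
    thr <- min_units[p]
    cand <- list()
    for (m in oracle_primitive_motifs(p)) {
      g <- gregexpr(paste0("(?:", m, "){", thr, ",}"), s, perl = TRUE)[[1L]]
      if (g[1L] == -1L) next
      lens <- attr(g, "match.length")
      for (j in seq_along(g)) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = as.integer(g[j]) - 1L, motif = m, period = p,
          units = lens[j] %/% p, stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$start), , drop = FALSE]
    prev_end <- 0L
    for (j in seq_len(nrow(cand))) {
      if (cand$start[j] < prev_end) next
      u <- cand$units[j]
      e <- cand$start[j] + u * p
      out[[length(out) + 1L]] <- data.frame(
        start = cand$start[j], end = e, motif = cand$motif[j], period = p,
        units = u, tract_length = u * p, stringsAsFactors = FALSE)
      prev_end <- e
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), period = integer(),
                      units = integer(), tract_length = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive repeat oracle: for every diagonal of the (S, transformed S)
# comparison, enumerate every window, keep those with <= k mismatches and
# length >= min_len that cannot be extended on either side
oracle_find_repeats <- function(s, min_len, k,
                                types = c("F", "R", "C", "P")) {
  ch <- oracle_chars(s)
  n <- length(ch)
  rows <- list()
  for (ty in types) {
    tch <- switch(ty, F = ch, C = oracle_comp(ch), R = rev(ch),
                  P = rev(oracle_comp(ch)))
    dmin <- if (ty %in% c("F", "C")) 1L else -(n - 1L)
    for (d in dmin:(n - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(n, n - d)
      len <- i1 - i0 + 1L
      if (len < min_len) next
      mm <- as.integer(ch[i0:i1] != tch[(i0:i1) + d])
      pre <- c(0L, cumsum(mm))
      cnt <- function(a, b) pre[b + 1L] - pre[a]  # window [a, b], 1-based
      for (a in seq_len(len - min_len + 1L)) {
        for (b in (a + min_len - 1L):len) {
          if (cnt(a, b) > k) break
          left_max <- a == 1L || cnt(a - 1L, b) > k
          right_max <- b == len || cnt(a, b + 1L) > k
          if (!(left_max && right_max)) next
          ws <- i0 + a - 1L; we <- i0 + b - 1L
          L <- we - ws + 1L
          if (ty %in% c("F", "C")) { s1 <- ws; s2 <- ws + d }
          else { s1 <- ws; s2 <- n + 1L - (we + d) }
          if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
          rows[[length(rows) + 1L]] <- data.frame(
            type = ty, start1 = s1 - 1L, end1 = s1 - 1L + L,
            start2 = s2 - 1L, end2 = s2 - 1L + L, length = L,
            mismatches = cnt(a, b), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(),
                      end2 = integer(), length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[!duplicated(paste(res$type, res$start1, res$start2,
                               res$length)), , drop = FALSE]
  res <- res[order(res$type, res$start1, res$start2, res$length), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-column nucleotide diversity oracle (complete deletion)
oracle_pi <- function(mat) {
  ok <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- mat[, ok, drop = FALSE]
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 0L
      for (c in seq_len(ncol(m))) if (m[i, c] != m[j, c]) d <- d + 1L
      total <- total + d / ncol(m)
    }
  }
  total / choose(n, 2L)
}

# per-pair p-distance oracle (pairwise deletion)
oracle_pdist <- function(mat, i, j) {
  nd <- 0L; nc <- 0L
  for (c in seq_len(ncol(mat))) {
    a <- mat[i, c]; b <- mat[j, c]
    if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
      nc <- nc + 1L
      if (a != b) nd <- nd + 1L
    }
  }
  c(n_diff = nd, p = nd / nc)
}

# exhaustive Fitch oracle: minimize substitutions over all internal-node
# state assignments, per column, summed over gap-free columns
oracle_fitch <- function(tree, mat) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  combos <- as.matrix(do.call(expand.grid, rep(list(bases), m)))
  edge <- tree$edge
  ok <- apply(mat, 2L, function(col) all(col %in% bases))
  cols <- which(ok)
  total <- 0L
  for (c in cols) {
    tipstate <- mat[tree$tip.label, c]
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      state <- c(tipstate, combos[r, ])
      sc <- sum(state[edge[, 1L]] != state[edge[, 2L]])
      if (sc < best) best <- sc
    }
    total <- total + best
  }
  total
}

# bipartition-set Robinson-Foulds oracle
oracle_rf <- function(t1, t2) {
  splits_of <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- length(tr$tip.label)
    tips_below <- function(node) {
      if (node <= ntip) return(node)
      kids <- tr$edge[tr$edge[, 1L] == node, 2L]
      unlist(lapply(kids, tips_below))
    }
    res <- character()
    for (e in seq_len(nrow(tr$edge))) {
      child <- tr$edge[e, 2L]
      if (child <= ntip) next  # trivial split
      tips <- tr$tip.label[tips_below(child)]
      side <- sort(tips)
      other <- sort(setdiff(tr$tip.label, tips))
      key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
        paste(side, collapse = ",") else paste(other, collapse = ",")
      res <- c(res, key)
    }
    unique(res)
  }
  s1 <- splits_of(t1); s2 <- splits_of(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# seeded random DNA string
rand_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# small random alignment with substitutions from a common ancestor
rand_alignment <- function(ntaxa, ncol, p_sub = 0.05, p_gap = 0.02) {
  anc <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  mat <- matrix(rep(anc, ntaxa), nrow = ntaxa, byrow = TRUE)
  for (i in seq_len(ntaxa)) {
    mut <- which(runif(ncol) < p_sub)
    mat[i, mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    gap <- which(runif(ncol) < p_gap)
    mat[i, gap] <- "-"
  }
  ids <- paste0("t", seq_len(ntaxa))
  alignment_matrix(ids, apply(mat, 1L, paste, collapse = ""))
}
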