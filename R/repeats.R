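# Maximal large-repeat finder at bounded Hamming distance. Four match types:
# forward (F), reverse (R), complement (C) and palindromic (P, i.e. reverse
# complement). A hit is a maximal pair: extending on either side would exceed
# the mismatch budget or run off the sequence. Detection is seed-and-extend:
# exact seeds of length floor(min_len / (max_mismatch + 1)) guarantee, by
# pigeonhole, that every qualifying window's comparison diagonal carries a
# seed inside the window.

#' Repeat search parameters
#'
#' Defaults mirror the REPuter-style settings used for plastome repeat
#' surveys: minimum copy length 30 bp and Hamming distance at most 3
#' (>= 90% identity).
#'
#' @param min_len Minimum repeat copy length in bp (>= 8).
#' @param max_mismatch Maximum Hamming distance (0-3 typical).
#' @param types Subset of `c("F", "R", "C", "P")`.
#' @return A `repeat_params` object.
#' @export
repeat_params <- function(min_len = 30L, max_mismatch = 3L,
                          types = c("F", "R", "C", "P")) {
  if (min_len < 8L) stop("min_len < 8 (seed degeneracy)", call. = FALSE)
  stopifnot(max_mismatch >= 0L, all(types %in% c("F", "R", "C", "P")))
  structure(list(min_len = as.integer(min_len),
                 max_mismatch = as.integer(max_mismatch),
                 types = types), class = "repeat_params")
}

#' Find maximal repeats at bounded Hamming distance
#'
#' Reports all maximal pairs of each requested type with copy length at least
#' `min_len` and at most `max_mismatch` mismatches, where `mismatches =
#' hamming(transform(copy2), copy1)` and the transform is identity (F),
#' reversal (R), complementation (C) or reverse-complementation (P).
#' Symmetric duplicates are reported once (`start1 <= start2`); the trivial
#' forward self-match is excluded.
#'
#' @param record A `seq_record` (or character scalar); ungapped.
#' @param params A [repeat_params()] object.
#' @return A data.frame with columns `type`, `start1`, `end1`, `start2`,
#'   `end2` (0-based half-open), `length`, `mismatches`.
#' @export
find_repeats <- function(record, params = repeat_params()) {
  s <- if (inherits(record, "seq_record")) record$seq else record
  if (grepl("-", s, fixed = TRUE)) stop("gap characters present", call. = FALSE)
  ch <- seq_chars(s)
  n <- length(ch)
  k <- params$max_mismatch
  w <- params$min_len %/% (k + 1L)
  out <- list()
  for (ty in params$types) {
    tch <- switch(ty,
                  F = ch,
                  C = complement_chars(ch),
                  R = rev(ch),
                  P = rev(complement_chars(ch)))
    hits <- scan_type(ch, tch, ty, w, params$min_len, k, n)
    if (nrow(hits)) out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) return(empty_repeat_hits())
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$type, res$start1, res$start2, res$length)), ,
             drop = FALSE]
  res <- res[order(res$type, res$start1, res$start2, res$length), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_repeat_hits <- function() {
  data.frame(type = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(), length = integer(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

# compare S[i] vs T[i + d] along diagonals carrying exact seeds
scan_type <- function(ch, tch, ty, w, min_len, k, n) {
  np <- n - w + 1L
  if (np < 1L) return(empty_repeat_hits())
  s_str <- chars_seq(ch); t_str <- chars_seq(tch)
  km_s <- substring(s_str, 1:np, (1:np) + w - 1L)
  km_t <- substring(t_str, 1:np, (1:np) + w - 1L)
  shared <- intersect(unique(km_s), unique(km_t))
  if (!length(shared)) return(empty_repeat_hits())
  pos_s <- split(seq_len(np), factor(km_s, levels = shared))
  pos_t <- split(seq_len(np), factor(km_t, levels = shared))
  pairs <- lapply(shared, function(word) {
    i <- pos_s[[word]]; u <- pos_t[[word]]
    cbind(i = rep(i, times = length(u)), u = rep(u, each = length(i)))
  })
  pairs <- do.call(rbind, pairs)
  d <- pairs[, "u"] - pairs[, "i"]
  if (ty %in% c("F", "C")) {
    keep <- d >= 1L
    pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  }
  if (!length(d)) return(empty_repeat_hits())
  res <- list()
  for (dd in unique(d)) {
    ii <- sort(unique(pairs[d == dd, "i"]))
    lo <- max(1L, 1L - dd); hi <- min(n, n - dd)
    wins <- diagonal_windows(ch, tch, dd, ii, w, k, lo, hi)
    if (is.null(wins)) next
    for (j in seq_len(nrow(wins))) {
      L <- wins$e[j] - wins$s[j] + 1L
      if (L < min_len) next
      res[[length(res) + 1L]] <-
        map_window(ty, wins$s[j], wins$e[j], dd, wins$mm[j], n)
    }
  }
  if (!length(res)) return(empty_repeat_hits())
  do.call(rbind, res)
}

# maximal <=k-mismatch windows on diagonal d that contain a seed; seeds given
# as start positions ii (exact w-mers). Returns data.frame(s, e, mm).
diagonal_windows <- function(ch, tch, dd, ii, w, k, lo, hi) {
  if (hi - lo + 1L < w) return(NULL)
  # merge seed intervals [i, i+w-1]
  iv_s <- ii; iv_e <- ii + w - 1L
  ord <- order(iv_s)
  ms <- iv_s[ord[1L]]; me <- iv_e[ord[1L]]
  merged <- list()
  for (j in ord[-1L]) {
    if (iv_s[j] <= me + 1L) me <- max(me, iv_e[j])
    else { merged[[length(merged) + 1L]] <- c(ms, me); ms <- iv_s[j]; me <- iv_e[j] }
  }
  merged[[length(merged) + 1L]] <- c(ms, me)
  out_s <- integer(); out_e <- integer(); out_m <- integer()
  for (iv in merged) {
    lmm <- scan_mismatches(ch, tch, dd, from = iv[1L] - 1L, step = -1L,
                           bound = lo, need = k + 1L)
    rmm <- scan_mismatches(ch, tch, dd, from = iv[2L] + 1L, step = 1L,
                           bound = hi, need = k + 1L)
    for (t in 0:k) {
      left <- if (t + 1L <= length(lmm)) lmm[t + 1L] + 1L else lo
      right <- if (k - t + 1L <= length(rmm)) rmm[k - t + 1L] - 1L else hi
      used_l <- min(t, length(lmm)); used_r <- min(k - t, length(rmm))
      out_s <- c(out_s, left); out_e <- c(out_e, right)
      out_m <- c(out_m, used_l + used_r)
    }
  }
  keep <- !duplicated(paste(out_s, out_e))
  out_s <- out_s[keep]; out_e <- out_e[keep]; out_m <- out_m[keep]
  # drop windows nested inside another (boundary-capped enumeration can
  # produce non-maximal duplicates)
  ord <- order(out_s, -out_e)
  out_s <- out_s[ord]; out_e <- out_e[ord]; out_m <- out_m[ord]
  best_e <- c(-Inf, cummax(out_e)[-length(out_e)])
  keep2 <- out_e > best_e
  data.frame(s = out_s[keep2], e = out_e[keep2], mm = out_m[keep2])
}

# positions of the first `need` mismatches scanning from `from` toward `bound`
scan_mismatches <- function(ch, tch, dd, from, step, bound, need,
                            chunk = 256L) {
  found <- integer()
  pos <- from
  while (length(found) < need) {
    if ((step > 0L && pos > bound) || (step < 0L && pos < bound)) break
    stop_at <- if (step > 0L) min(bound, pos + chunk - 1L)
               else max(bound, pos - chunk + 1L)
    idx <- seq(pos, stop_at, by = step)
    mm <- idx[ch[idx] != tch[idx + dd]]
    found <- c(found, mm)
    pos <- stop_at + step
  }
  found[seq_len(min(length(found), need))]
}

# map a diagonal window [ws, we] (positions in S, 1-based) to copy intervals
map_window <- function(ty, ws, we, dd, mm, n) {
  L <- we - ws + 1L
  if (ty %in% c("F", "C")) {
    s1 <- ws; s2 <- ws + dd
  } else {
    s1 <- ws
    s2 <- n + 1L - (we + dd)
  }
  if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
  data.frame(type = ty, start1 = s1 - 1L, end1 = s1 - 1L + L,
             start2 = s2 - 1L, end2 = s2 - 1L + L,
             length = L, mismatches = mm, stringsAsFactors = FALSE)
}

#' Exclude the genome's own IR pair from repeat hits
#'
#' The annotated IRa/IRb pair of a plastome would otherwise dominate the
#' repeat survey as one giant palindromic hit. Removes hits whose two copies
#' are the IRa/IRb intervals themselves (or whose copies lie fully inside
#' IRa and IRb at mirrored positions).
#'
#' @param hits Repeat hit data.frame.
#' @param partition A `region_partition`.
#' @return Filtered hit data.frame.
#' @export
exclude_ir_mirror <- function(hits, partition) {
  if (!nrow(hits)) return(hits)
  ira <- partition$ira; irb <- partition$irb
  mirrored <- hits$type == "P" &
    hits$start1 >= ira[1L] & hits$end1 <= ira[2L] &
    hits$start2 >= irb[1L] & hits$end2 <= irb[2L] &
    (hits$start2 - irb[1L]) == (ira[2L] - hits$end1)
  hits[!mirrored, , drop = FALSE]
}

#' Collapse repeat hits into loci
#'
#' Repeats with the same type and length whose copies lie in the same
#' region combination are regarded as one repeat locus.
#'
#' @param hits Repeat hit data.frame.
#' @param partition A `region_partition` used to assign copy regions.
#' @return A data.frame with one row per locus: `type`, `length`, `regions`
#'   (sorted copy-region pair) and `members`.
#' @export
collapse_loci <- function(hits, partition) {
  if (!nrow(hits)) {
    return(data.frame(type = character(), length = integer(),
                      regions = character(), members = integer(),
                      stringsAsFactors = FALSE))
  }
  r1 <- vapply(seq_len(nrow(hits)), function(i) {
    region_of(partition, hits$start1[i], hits$end1[i])
  }, "")
  r2 <- vapply(seq_len(nrow(hits)), function(i) {
    region_of(partition, hits$start2[i], hits$end2[i])
  }, "")
  regs <- vapply(seq_len(nrow(hits)), function(i) {
    paste(sort(c(r1[i], r2[i])), collapse = "+")
  }, "")
  key <- paste(hits$type, hits$length, regs, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(type = vapply(parts, `[[`, "", 1L),
                    length = as.integer(vapply(parts, `[[`, "", 2L)),
                    regions = vapply(parts, `[[`, "", 3L),
                    members = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$type, out$length, out$regions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeat length/type histogram
#'
#' Counts binned by copy length classes 30-39, 40-49, 50-59 and >= 60 bp,
#' and by repeat type.
#'
#' @param hits Repeat hit (or locus) data.frame with `type` and `length`.
#' @return A data.frame with one row per type plus a `total` row; columns are
#'   the length bins and a row total.
#' @export
repeat_histogram <- function(hits) {
  bins <- c("30-39", "40-49", "50-59", ">=60")
  bin_of <- function(L) {
    ifelse(L < 40L, "30-39",
           ifelse(L < 50L, "40-49", ifelse(L < 60L, "50-59", ">=60")))
  }
  types <- c("F", "R", "C", "P")
  rows <- lapply(c(types, "total"), function(ty) {
    sub <- if (ty == "total") hits else hits[hits$type == ty, , drop = FALSE]
    counts <- integer(length(bins))
    if (nrow(sub)) {
      tb <- table(factor(bin_of(sub$length), levels = bins))
      counts <- as.integer(tb)
    }
    data.frame(type = ty, `30-39` = counts[1L], `40-49` = counts[2L],
               `50-59` = counts[3L], `>=60` = counts[4L],
               total = sum(counts), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
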