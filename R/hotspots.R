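# Sliding-window divergence profiling and extraction of highly variable
# regions: windows whose polymorphic-site count S exceeds mean(S) plus
# k_sd standard deviations are merged into hotspot intervals.

#' Sliding-window parameters
#'
#' @param window_length Window length in alignment columns (default 600).
#' @param step Step size in columns (default 200).
#' @param k_sd Threshold multiplier on the standard deviation (default 2).
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`.
#' @return A `window_params` object.
#' @export
window_params <- function(window_length = 600L, step = 200L, k_sd = 2,
                          sd_type = c("population", "sample")) {
  if (window_length < 100L) stop("window_length < 100", call. = FALSE)
  if (step > window_length) stop("step > window_length", call. = FALSE)
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step), k_sd = k_sd,
                 sd_type = match.arg(sd_type)), class = "window_params")
}

#' Sliding-window diversity scan
#'
#' Windows are anchored on alignment columns starting at 0, `step`,
#' 2 x `step`, ...; a final window shorter than `window_length` is truncated
#' at the alignment end, included and flagged. Per-window `S` and `pi` come
#' from [diversity_stats()] on the window's columns; windows with no
#' analyzable column get `S = 0` and `pi = NA`.
#'
#' @param alignment An `alignment_matrix`.
#' @param params A [window_params()] object.
#' @return A data.frame with `start`, `end` (0-based half-open columns),
#'   `midpoint`, `S`, `pi`, `truncated`.
#' @export
window_scan <- function(alignment, params = window_params()) {
  len <- alignment$length
  wl <- params$window_length
  if (len < wl) {
    warning("alignment (", len, " columns) shorter than window length (",
            wl, "); single truncated window", call. = FALSE)
    starts <- 0L
  } else {
    starts <- seq.int(0L, len - 1L, by = params$step)
  }
  rows <- lapply(starts, function(s0) {
    e0 <- min(s0 + wl, len)
    st <- tryCatch(diversity_stats(alignment, seq.int(s0, e0 - 1L)),
                   error = function(e) list(S = 0L, pi = NA_real_))
    data.frame(start = s0, end = e0, midpoint = (s0 + e0) / 2,
               S = st$S, pi = st$pi, truncated = (e0 - s0) < wl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select hotspot intervals from a window profile
#'
#' The threshold is `T = mean(S) + k_sd * sd(S)` over all windows (population
#' standard deviation by default); windows with `S > T` (strict) are
#' selected, and overlapping or exactly abutting selected windows are merged
#' into maximal intervals. Windows separated by an unselected gap are not
#' merged.
#'
#' @param windows Data.frame from [window_scan()].
#' @param params A [window_params()] object (supplies `k_sd` and `sd_type`).
#' @return A data.frame of merged intervals: `start`, `end` (0-based
#'   half-open columns), `n_windows`.
#' @export
select_hotspots <- function(windows, params = window_params()) {
  if (nrow(windows) < 2L) {
    stop("need >= 2 windows to define a threshold (sd undefined)",
         call. = FALSE)
  }
  s <- windows$S
  sdv <- if (params$sd_type == "population") pop_sd(s) else stats::sd(s)
  thr <- mean(s) + params$k_sd * sdv
  sel <- windows[s > thr, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(start = integer(), end = integer(),
                      n_windows = integer()))
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  out_s <- sel$start[1L]; out_e <- sel$end[1L]; cnt <- 1L
  res <- list()
  for (i in seq_len(nrow(sel))[-1L]) {
    if (sel$start[i] <= out_e) {  # overlap or exact abutment
      out_e <- max(out_e, sel$end[i]); cnt <- cnt + 1L
    } else {
      res[[length(res) + 1L]] <- data.frame(start = out_s, end = out_e,
                                            n_windows = cnt)
      out_s <- sel$start[i]; out_e <- sel$end[i]; cnt <- 1L
    }
  }
  res[[length(res) + 1L]] <- data.frame(start = out_s, end = out_e,
                                        n_windows = cnt)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate hotspot intervals against a reference genome
#'
#' Maps each alignment interval to reference coordinates through the
#' reference row, names it from the annotation (the gene it falls in; `a`/`b`
#' suffixes when one gene yields several disjoint regions; flanking genes
#' joined by `-` for intergenic spans, with any genes overlapped along the
#' way included in the join), and computes per-region divergence statistics
#' on the interval's columns.
#'
#' @param intervals Data.frame from [select_hotspots()].
#' @param alignment An `alignment_matrix`.
#' @param features Feature list on the reference genome's canonical
#'   coordinates.
#' @param reference_id Reference row id.
#' @return A data.frame: `name`, `col_start`, `col_end`, `ref_start`,
#'   `ref_end` (0-based half-open on the reference), `length` (columns),
#'   `S`, `PI`, `pi`.
#' @export
annotate_hotspots <- function(intervals, alignment, features, reference_id) {
  if (!(reference_id %in% alignment$ids)) {
    stop("reference id '", reference_id, "' not in alignment", call. = FALSE)
  }
  map <- ungapped_to_columns(alignment$mat[reference_id, ])
  spans <- if (length(features)) {
    data.frame(gene = vapply(features, `[[`, "", "name"),
               start = vapply(features, function(f) min(f$parts$start), 0L),
               end = vapply(features, function(f) max(f$parts$end), 0L))
  } else data.frame(gene = character(), start = integer(), end = integer())
  spans <- spans[order(spans$start), , drop = FALSE]
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    cs <- intervals$start[i]; ce <- intervals$end[i]
    # reference bases whose columns fall inside [cs, ce)
    inside <- which(map >= cs & map < ce)
    if (!length(inside)) {
      rs <- re <- NA_integer_
      name <- "unmapped"
    } else {
      rs <- min(inside) - 1L; re <- max(inside)
      name <- hotspot_name(rs, re, spans)
    }
    st <- tryCatch(diversity_stats(alignment, seq.int(cs, ce - 1L)),
                   error = function(e) list(S = 0L, PI = 0L, pi = NA_real_))
    data.frame(name = name, col_start = cs, col_end = ce,
               ref_start = rs, ref_end = re, length = ce - cs,
               S = st$S, PI = st$PI, pi = st$pi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # a/b suffixes when one gene produced several disjoint regions
  dup <- names(table(out$name))[table(out$name) > 1L]
  for (nm in dup) {
    idx <- which(out$name == nm)
    out$name[idx] <- paste0(nm, letters[seq_along(idx)])
  }
  out
}

# name an interval [rs, re) from gene spans: gene name if fully inside one
# gene, otherwise flanking/overlapped genes joined with "-"
hotspot_name <- function(rs, re, spans) {
  if (!nrow(spans)) return("unannotated")
  within <- which(spans$start <= rs & spans$end >= re)
  if (length(within)) return(spans$gene[within[1L]])
  overlapped <- which(pmin(spans$end, re) - pmax(spans$start, rs) > 0L)
  left <- which(spans$end <= rs)
  right <- which(spans$start >= re)
  parts <- character()
  if (!length(overlapped) || min(spans$start[overlapped]) > rs) {
    if (length(left)) {
      parts <- c(parts, spans$gene[left[which.max(spans$end[left])]])
    }
  }
  if (length(overlapped)) {
    parts <- c(parts, spans$gene[overlapped[order(spans$start[overlapped])]])
  }
  if (!length(overlapped) || max(spans$end[overlapped]) < re) {
    if (length(right)) {
      parts <- c(parts, spans$gene[right[which.min(spans$start[right])]])
    }
  }
  if (!length(parts)) return("unannotated")
  paste(unique(parts), collapse = "-")
}
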