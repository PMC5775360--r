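# Perfect microsatellite (SSR) scanner with MISA-style unit-count thresholds.
# A hit is a maximal perfect tandem run of a primitive motif, truncated to
# whole units; reported period is the minimal period of the tract.

#' SSR detection thresholds
#'
#' Minimum repeat-unit counts per motif period, defaulting to the MISA-style
#' thresholds: ten units for mononucleotides, five for dinucleotides, four for
#' trinucleotides and three for tetra-, penta- and hexanucleotides.
#'
#' @param min_units Named integer vector: minimum unit count for periods 1-6.
#' @return An `ssr_params` object.
#' @export
ssr_params <- function(min_units = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                     `4` = 3L, `5` = 3L, `6` = 3L)) {
  stopifnot(length(min_units) == 6L, all(min_units >= 2L))
  structure(list(min_units = as.integer(min_units)), class = "ssr_params")
}

# is motif primitive (minimal period equals its length)?
motif_is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q != 0L) next
    unit <- substr(motif, 1L, q)
    if (identical(strrep(unit, p %/% q), motif)) return(FALSE)
  }
  TRUE
}

#' Find perfect SSRs in a sequence
#'
#' Scans for all maximal perfect tandem repeats with minimal period 1-6 whose
#' whole-unit count meets the period's threshold. Tracts are reported at their
#' minimal period only (`ATATATATAT` is `(AT)5`, never `(ATAT)2`), truncated
#' to whole units, and no two reported hits overlap at the same minimal
#' period.
#'
#' @param record A `seq_record` (or character scalar); must be ungapped.
#' @param params An [ssr_params()] object.
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `motif`, `period`, `units`, `tract_length`.
#' @export
find_ssrs <- function(record, params = ssr_params()) {
  s <- if (inherits(record, "seq_record")) record$seq else record
  if (grepl("-", s, fixed = TRUE)) {
    stop("gap characters present; SSR scan requires an ungapped sequence",
         call. = FALSE)
  }
  ch <- seq_chars(s)
  n <- length(ch)
  hits <- list()
  for (p in 1:6) {
    thr <- params$min_units[[p]]
    if (n < p * thr) next
    eq <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p]
    runs <- true_runs(eq)
    if (!nrow(runs)) next
    # a p-periodic run of matches [i, j) covers tract span [i, j + p);
    # adjacent runs may overlap by < p bases, so consume left-to-right
    prev_end <- 0L
    for (ri in seq_len(nrow(runs))) {
      span_end <- runs$end[ri] + p
      tract_start <- max(runs$start[ri], prev_end)
      units <- (span_end - tract_start) %/% p
      if (units < thr) next
      motif <- substr(s, tract_start + 1L, tract_start + p)
      if (!motif_is_primitive(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = tract_start, end = tract_start + units * p,
        motif = motif, period = p, units = units,
        tract_length = units * p, stringsAsFactors = FALSE)
      prev_end <- tract_start + units * p
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      period = integer(), units = integer(),
                      tract_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign region and genomic context to SSR hits
#'
#' Region is by interval containment in the partition (hits crossing a region
#' boundary are labelled `junction-spanning`). Context is `CDS` if the tract
#' overlaps a CDS exon by at least 1 bp, else `intron` if it lies inside an
#' annotated gene between exons, else `IGS`. tRNA/rRNA bodies without exon
#' substructure count as `IGS` unless inside a CDS or annotated intron.
#'
#' @param hits Data.frame from [find_ssrs()].
#' @param features Feature list on canonical coordinates.
#' @param partition A `region_partition`.
#' @return `hits` with `region`, `context` and `gene` columns added.
#' @export
contextualize_ssrs <- function(hits, features, partition) {
  if (!nrow(hits)) {
    hits$region <- character(); hits$context <- character()
    hits$gene <- character()
    return(hits)
  }
  hits$region <- vapply(seq_len(nrow(hits)), function(i) {
    region_of(partition, hits$start[i], hits$end[i])
  }, "")
  ctx <- character(nrow(hits)); gene <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    a <- hits$start[i]; b <- hits$end[i]
    cls <- classify_interval(a, b, features)
    ctx[i] <- cls$context; gene[i] <- cls$gene
  }
  hits$context <- ctx
  hits$gene <- gene
  hits
}

# context of interval [a, b): CDS > intron > IGS
classify_interval <- function(a, b, features) {
  in_cds <- character(); in_intron <- character()
  for (f in features) {
    p <- f$parts
    if (f$kind == "CDS" && any(pmin(b, p$end) - pmax(a, p$start) > 0L)) {
      in_cds <- c(in_cds, f$name)
      next
    }
    if (nrow(p) > 1L) {  # inside the gene body between exons?
      span_lo <- min(p$start); span_hi <- max(p$end)
      if (a >= span_lo && b <= span_hi &&
          !any(pmin(b, p$end) - pmax(a, p$start) > 0L)) {
        in_intron <- c(in_intron, f$name)
      }
    }
  }
  if (length(in_cds)) {
    list(context = "CDS", gene = paste(unique(in_cds), collapse = "/"))
  } else if (length(in_intron)) {
    list(context = "intron", gene = paste(unique(in_intron), collapse = "/"))
  } else {
    list(context = "IGS", gene = "")
  }
}

# cumulative map from ungapped positions to alignment columns for one row
# (both 0-based); returns integer vector: column of each ungapped base
ungapped_to_columns <- function(row_chars) {
  which(row_chars != "-") - 1L
}

#' Call alignment-anchored SSR loci across species
#'
#' Each species' hits are projected to alignment columns through that row's
#' ungapped-to-aligned coordinate map; hits whose column intervals overlap
#' (single linkage) are merged into one locus. A locus is polymorphic iff at
#' least two species have distinct tract descriptors, counting absence.
#'
#' @param alignment An `alignment_matrix` whose rows are the species genomes.
#' @param per_species_hits Named list (by species id) of hit data.frames from
#'   [find_ssrs()], on each species' ungapped coordinates.
#' @return A data.frame with one row per locus: `col_start`, `col_end`
#'   (0-based half-open alignment columns), `n_species_present`,
#'   `polymorphic`, and `descriptors` (per-species `motif x units` strings,
#'   `absent` for species without an overlapping hit).
#' @export
ssr_loci <- function(alignment, per_species_hits) {
  ids <- names(per_species_hits)
  missing <- setdiff(ids, alignment$ids)
  if (length(missing)) {
    stop("species not in alignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  proj <- list()
  for (id in ids) {
    hits <- per_species_hits[[id]]
    if (!nrow(hits)) next
    map <- ungapped_to_columns(alignment$mat[id, ])
    if (max(hits$end) > length(map)) {
      stop("hits for '", id, "' exceed its ungapped length", call. = FALSE)
    }
    proj[[length(proj) + 1L]] <- data.frame(
      species = id,
      col_start = map[hits$start + 1L],
      col_end = map[hits$end] + 1L,   # column after the tract's last base
      desc = paste0(hits$motif, "x", hits$units),
      stringsAsFactors = FALSE)
  }
  if (!length(proj)) {
    return(data.frame(col_start = integer(), col_end = integer(),
                      n_species_present = integer(), polymorphic = logical(),
                      descriptors = character(), stringsAsFactors = FALSE))
  }
  proj <- do.call(rbind, proj)
  proj <- proj[order(proj$col_start, proj$col_end), , drop = FALSE]
  # single-linkage merge of overlapping column intervals
  comp <- integer(nrow(proj)); comp[1L] <- 1L
  hi <- proj$col_end[1L]
  for (i in seq_len(nrow(proj))[-1L]) {
    if (proj$col_start[i] < hi) comp[i] <- comp[i - 1L]
    else comp[i] <- comp[i - 1L] + 1L
    hi <- max(hi, proj$col_end[i])
  }
  all_ids <- names(per_species_hits)
  loci <- lapply(split(proj, comp), function(g) {
    desc <- setNames(rep("absent", length(all_ids)), all_ids)
    for (i in seq_len(nrow(g))) desc[[g$species[i]]] <- g$desc[i]
    data.frame(col_start = min(g$col_start), col_end = max(g$col_end),
               n_species_present = length(unique(g$species)),
               polymorphic = length(unique(desc)) >= 2L,
               descriptors = paste(paste0(all_ids, ":", desc), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Summarize SSR hits per genome
#'
#' Counts by period class (mono- through hexanucleotide), by genomic context
#' and by region, mirroring the layout of per-genome SSR summary tables.
#'
#' @param hits Contextualized hit data.frame (see [contextualize_ssrs()]).
#' @param genome_id Label for the `genome` column.
#' @return A one-row data.frame of counts.
#' @export
ssr_summary <- function(hits, genome_id = "genome") {
  count_p <- function(p) if (nrow(hits)) sum(hits$period == p) else 0L
  has_ctx <- nrow(hits) > 0L && "context" %in% names(hits)
  count_c <- function(ctx) if (has_ctx) sum(hits$context == ctx) else 0L
  count_r <- function(rg) {
    if (has_ctx && "region" %in% names(hits)) sum(hits$region %in% rg) else 0L
  }
  data.frame(genome = genome_id, total = nrow(hits),
             mono = count_p(1L), di = count_p(2L), tri = count_p(3L),
             tetra = count_p(4L), penta = count_p(5L), hexa = count_p(6L),
             IGS = count_c("IGS"), intron = count_c("intron"),
             CDS = count_c("CDS"),
             LSC = count_r("LSC"), IR = count_r(c("IRa", "IRb")),
             SSC = count_r("SSC"),
             junction = count_r("junction-spanning"),
             stringsAsFactors = FALSE)
}
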