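# End-to-end comparative pipeline: genome summaries, junction analysis, SSR
# and repeat surveys, divergence statistics, hotspot discovery and an NJ
# tree, written as TSV reports. All coordinates in reports are 1-based
# inclusive; internal work is 0-based half-open. The pipeline contains no
# randomness: identical inputs give byte-identical outputs.

#' Pipeline configuration
#'
#' @param genomes Path to a multi-FASTA of the genomes, or a named list of
#'   `seq_record`.
#' @param features Path to a GFF3/flat feature table on the reference
#'   genome's canonical coordinates, or a feature list.
#' @param alignment Path to the whole-genome aligned FASTA (row ids must
#'   match the genome ids), or an `alignment_matrix`.
#' @param reference Id of the reference genome (region projection, hotspot
#'   annotation).
#' @param out_dir Output directory for the TSV reports.
#' @param ssr [ssr_params()].
#' @param repeats [repeat_params()] (applied at each Hamming distance of
#'   `hamming_sweep`).
#' @param window [window_params()].
#' @param min_ir_len Minimum IR length for quadripartite detection.
#' @param hamming_sweep Hamming distances at which the repeat survey runs.
#' @param exclude_ir_repeats Drop the genome's own IRa/IRb mirror hits from
#'   repeat summaries.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(genomes, features, alignment, reference, out_dir,
                            ssr = ssr_params(), repeats = repeat_params(),
                            window = window_params(), min_ir_len = 1000L,
                            hamming_sweep = 0:3, exclude_ir_repeats = TRUE) {
  structure(list(genomes = genomes, features = features,
                 alignment = alignment, reference = reference,
                 out_dir = out_dir, ssr = ssr, repeats = repeats,
                 window = window, min_ir_len = as.integer(min_ir_len),
                 hamming_sweep = hamming_sweep,
                 exclude_ir_repeats = exclude_ir_repeats),
            class = "pipeline_config")
}

#' Run the comparative pipeline
#'
#' Executes every stage and writes the report files into `out_dir`:
#' `genome_summary.tsv`, `junctions.tsv`, `partition.bed`, `ssr_hits.tsv`,
#' `ssr_summary.tsv`, `ssr_loci.tsv`, `repeats.tsv`, `repeat_loci.tsv`,
#' `repeat_histogram.tsv`, `region_stats.tsv`, `distances.tsv`,
#' `window_profile.tsv`, `hotspots.tsv`, `nj_tree.nwk` and `run_log.txt`.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list of the computed tables.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("plastidkit pipeline"),
                 paste("min_ir_len:", cfg$min_ir_len),
                 paste("ssr thresholds:",
                       paste(cfg$ssr$min_units, collapse = ",")),
                 paste("repeat min_len:", cfg$repeats$min_len),
                 paste("hamming sweep:", paste(cfg$hamming_sweep, collapse = ",")),
                 paste("window:", cfg$window$window_length, "step:",
                       cfg$window$step, "k_sd:", cfg$window$k_sd,
                       "sd:", cfg$window$sd_type),
                 paste("exclude IR mirror repeats:", cfg$exclude_ir_repeats))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genomes <- stage("read_genomes", {
    if (is.character(cfg$genomes)) read_fasta(cfg$genomes, circular = TRUE)
    else cfg$genomes
  })
  features <- stage("read_features", {
    if (is.character(cfg$features)) read_features(cfg$features)
    else cfg$features
  })
  aln <- stage("read_alignment", {
    if (is.character(cfg$alignment)) read_alignment(cfg$alignment)
    else cfg$alignment
  })
  if (!(cfg$reference %in% names(genomes))) {
    stop("pipeline stage 'read_genomes' failed: reference '", cfg$reference,
         "' not among genome ids", call. = FALSE)
  }

  # --- quadripartite structure, per genome ------------------------------
  quadri <- stage("partition", {
    lapply(genomes, function(g) {
      suppressWarnings(detect_quadripartite(g, cfg$min_ir_len, features))
    })
  })
  summary_rows <- list(); junction_rows <- list(); bed_rows <- list()
  ssr_hit_rows <- list(); ssr_sum_rows <- list()
  rep_rows <- list(); rep_locus_rows <- list(); rep_hist_rows <- list()
  per_species_hits <- list()
  for (id in names(genomes)) {
    q <- quadri[[id]]
    part <- q$partition
    feats_g <- transform_features(features, q$transform, part$genome_length)
    n <- part$genome_length
    kinds <- vapply(features, `[[`, "", "kind")
    summary_rows[[id]] <- data.frame(
      genome = id, length = n,
      lsc = part$lsc[2L] - part$lsc[1L], ir = part$ira[2L] - part$ira[1L],
      ssc = part$ssc[2L] - part$ssc[1L],
      at_percent = round(100 * at_content(q$record), 2L),
      cds = sum(kinds == "CDS"), trna = sum(kinds == "tRNA"),
      rrna = sum(kinds == "rRNA"), stringsAsFactors = FALSE)
    jt <- stage("junctions", junction_table(part, feats_g))
    jt <- cbind(genome = id, jt)
    junction_rows[[id]] <- jt
    bed <- partition_bed(part, id)
    bed_rows[[id]] <- bed

    # --- SSRs ----------------------------------------------------------
    hits <- stage("ssr", {
      contextualize_ssrs(find_ssrs(q$record, cfg$ssr), feats_g, part)
    })
    if (nrow(hits)) {
      ssr_hit_rows[[id]] <- cbind(genome = id,
                                  hits[, c("start", "end", "motif", "period",
                                           "units", "region", "context",
                                           "gene")])
      ssr_hit_rows[[id]]$start <- ssr_hit_rows[[id]]$start + 1L  # 1-based
    }
    ssr_sum_rows[[id]] <- ssr_summary(hits, id)
    per_species_hits[[id]] <- find_ssrs(genomes[[id]], cfg$ssr)

    # --- large repeats, Hamming sweep ----------------------------------
    for (k in cfg$hamming_sweep) {
      rp <- repeat_params(cfg$repeats$min_len, k, cfg$repeats$types)
      rhits <- stage("repeats", find_repeats(q$record, rp))
      if (cfg$exclude_ir_repeats) rhits <- exclude_ir_mirror(rhits, part)
      if (nrow(rhits)) {
        tagged <- cbind(genome = id, hamming = k, rhits)
        tagged$start1 <- tagged$start1 + 1L
        tagged$start2 <- tagged$start2 + 1L
        rep_rows[[length(rep_rows) + 1L]] <- tagged
      }
      loci <- collapse_loci(rhits, part)
      if (nrow(loci)) {
        rep_locus_rows[[length(rep_locus_rows) + 1L]] <-
          cbind(genome = id, hamming = k, loci)
      }
      rep_hist_rows[[length(rep_hist_rows) + 1L]] <-
        cbind(genome = id, hamming = k, repeat_histogram(rhits))
    }
  }

  # --- alignment statistics --------------------------------------------
  ref_part <- quadri[[cfg$reference]]$partition
  region_stats <- stage("stats", {
    region_stats_table(aln, cfg$reference, ref_part)
  })
  dm <- stage("distance", distance_matrix(aln))
  loci_tab <- stage("ssr_loci", ssr_loci(aln, per_species_hits))
  windows <- stage("windows", window_scan(aln, cfg$window))
  hot_iv <- stage("hotspots", select_hotspots(windows, cfg$window))
  ref_feats <- transform_features(features, quadri[[cfg$reference]]$transform,
                                  ref_part$genome_length)
  hot_tab <- stage("hotspots", {
    annotate_hotspots(hot_iv, aln, ref_feats, cfg$reference)
  })
  tree <- if (length(aln$ids) >= 3L) stage("tree", nj_tree(dm)) else NULL

  # --- write reports ----------------------------------------------------
  out <- function(x, f) write_report(x, file.path(cfg$out_dir, f))
  out(do.call(rbind, summary_rows), "genome_summary.tsv")
  out(do.call(rbind, junction_rows), "junctions.tsv")
  out(do.call(rbind, bed_rows), "partition.bed")
  ssr_hits_all <- if (length(ssr_hit_rows)) do.call(rbind, ssr_hit_rows)
                  else data.frame(genome = character())
  out(ssr_hits_all, "ssr_hits.tsv")
  out(do.call(rbind, ssr_sum_rows), "ssr_summary.tsv")
  loci_out <- loci_tab
  if (nrow(loci_out)) loci_out$col_start <- loci_out$col_start + 1L
  out(loci_out, "ssr_loci.tsv")
  out(if (length(rep_rows)) do.call(rbind, rep_rows)
      else data.frame(genome = character()), "repeats.tsv")
  out(if (length(rep_locus_rows)) do.call(rbind, rep_locus_rows)
      else data.frame(genome = character()), "repeat_loci.tsv")
  out(do.call(rbind, rep_hist_rows), "repeat_histogram.tsv")
  out(region_stats, "region_stats.tsv")
  out(distance_report(dm), "distances.tsv")
  wt <- windows; wt$start <- wt$start + 1L
  out(wt, "window_profile.tsv")
  hot_out <- hot_tab
  if (nrow(hot_out)) {
    hot_out$col_start <- hot_out$col_start + 1L
    hot_out$ref_start <- hot_out$ref_start + 1L
  }
  out(hot_out, "hotspots.tsv")
  if (!is.null(tree)) {
    ape::write.tree(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  } else {
    log_lines <- c(log_lines, "tree stage skipped: fewer than 3 taxa")
  }
  n_trunc <- sum(windows$truncated)
  log_lines <- c(log_lines, paste("genomes:", length(genomes)),
                 paste("alignment columns:", aln$length),
                 paste("truncated windows:", n_trunc),
                 paste("hotspot regions:", nrow(hot_tab)))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(summary = do.call(rbind, summary_rows),
                 junctions = do.call(rbind, junction_rows),
                 ssr_hits = ssr_hits_all,
                 ssr_summary = do.call(rbind, ssr_sum_rows),
                 ssr_loci = loci_tab,
                 repeats = if (length(rep_rows)) do.call(rbind, rep_rows)
                           else NULL,
                 repeat_histogram = do.call(rbind, rep_hist_rows),
                 region_stats = region_stats, distances = dm,
                 windows = windows, hotspots = hot_tab, tree = tree))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param bundle A full truth bundle from [simulate_dataset()].
#' @param dir Output directory.
#' @return The directory, invisibly; writes `genomes.fasta`,
#'   `alignment.fasta`, `features.gff3`, `tree.nwk` and per-element truth
#'   TSVs.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$species, file.path(dir, "genomes.fasta"))
  write_alignment(bundle$alignment, file.path(dir, "alignment.fasta"))
  write_features_gff3(bundle$features, file.path(dir, "features.gff3"),
                      seqid = "genome")
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_report(bundle$ssr_truth, file.path(dir, "truth_ssrs.tsv"))
  write_report(bundle$repeat_truth, file.path(dir, "truth_repeats.tsv"))
  write_report(bundle$hotspot_truth, file.path(dir, "truth_hotspots.tsv"))
  invisible(dir)
}
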