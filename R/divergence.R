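# Alignment divergence statistics: column classification, variable and
# parsimony-informative site counts, nucleotide diversity (Nei's pi) under
# complete deletion, and uncorrected p-distances under pairwise deletion.
# Ambiguity codes other than N are treated as N.

ALN_OK <- c("A", "C", "G", "T")

clean_mat <- function(alignment) {
  mat <- alignment$mat
  mat[!(mat %in% c(ALN_OK, "-"))] <- "N"
  mat
}

#' Classify alignment columns
#'
#' Each column is labelled `excluded` (any row has a gap or `N`), `invariant`,
#' `variable` (two or more distinct bases) or `parsimony-informative` (two or
#' more distinct bases each present in at least two rows; implies variable).
#'
#' @param alignment An `alignment_matrix`.
#' @return Character vector of per-column labels.
#' @export
column_classes <- function(alignment) {
  mat <- clean_mat(alignment)
  classify_columns_mat(mat)
}

# vectorized per-column classification of a cleaned character matrix
classify_columns_mat <- function(mat) {
  excluded <- colSums(mat == "-" | mat == "N") > 0L
  counts <- vapply(ALN_OK, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L)
  distinct <- rowSums(counts > 0L)
  pi_bases <- rowSums(counts >= 2L)
  out <- rep("invariant", ncol(mat))
  out[distinct >= 2L] <- "variable"
  out[distinct >= 2L & pi_bases >= 2L] <- "parsimony-informative"
  out[excluded] <- "excluded"
  out
}

#' Divergence statistics over an alignment (or a column subset)
#'
#' Uses complete deletion: columns containing any gap or `N` are excluded
#' from the analysis. Nucleotide diversity is the mean pairwise p-distance
#' over the analyzed columns, `pi = sum_{i<j} d_ij / C(n,2)`.
#'
#' @param alignment An `alignment_matrix`.
#' @param column_subset Optional integer vector of 0-based column indices
#'   restricting the analysis (defaults to all columns).
#' @return A list: `raw_columns` (columns considered), `sites` (analyzed,
#'   i.e. gap/N-free, columns), `S` (variable sites), `PI`
#'   (parsimony-informative sites), `pi` (nucleotide diversity).
#' @export
diversity_stats <- function(alignment, column_subset = NULL) {
  mat <- clean_mat(alignment)
  if (!is.null(column_subset)) {
    mat <- mat[, column_subset + 1L, drop = FALSE]
  }
  raw <- ncol(mat)
  analyzed <- colSums(mat == "-" | mat == "N") == 0L
  m <- mat[, analyzed, drop = FALSE]
  if (ncol(m) == 0L) {
    stop("no analyzable columns (all contain gaps or N)", call. = FALSE)
  }
  cls <- classify_columns_mat(m)
  nrows <- nrow(m)
  total_d <- 0
  npairs <- 0L
  for (i in seq_len(nrows - 1L)) {
    for (j in (i + 1L):nrows) {
      total_d <- total_d + sum(m[i, ] != m[j, ]) / ncol(m)
      npairs <- npairs + 1L
    }
  }
  list(raw_columns = raw, sites = ncol(m),
       S = sum(cls %in% c("variable", "parsimony-informative")),
       PI = sum(cls == "parsimony-informative"),
       pi = total_d / npairs)
}

#' Pairwise p-distance and nucleotide-difference matrices
#'
#' Uses pairwise deletion: for each sequence pair only columns where both
#' rows carry an unambiguous base are compared. `p_distance = n_diff /
#' compared columns`.
#'
#' @param alignment An `alignment_matrix`.
#' @return A list of class `distance_matrix` with `ids`, `p_distance` and
#'   `n_diff` (symmetric matrices, zero diagonal).
#' @export
distance_matrix <- function(alignment) {
  mat <- clean_mat(alignment)
  n <- nrow(mat)
  if (n < 2L) stop("need >= 2 rows", call. = FALSE)
  good <- mat %in% ALN_OK
  dim(good) <- dim(mat)
  p <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  d <- matrix(0L, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- good[i, ] & good[j, ]
      nc <- sum(both)
      if (nc == 0L) {
        stop("pair ", alignment$ids[i], "/", alignment$ids[j],
             " has zero comparable columns", call. = FALSE)
      }
      nd <- sum(mat[i, both] != mat[j, both])
      d[i, j] <- d[j, i] <- nd
      p[i, j] <- p[j, i] <- nd / nc
    }
  }
  structure(list(ids = alignment$ids, p_distance = p, n_diff = d),
            class = "distance_matrix")
}

#' Project a reference genome's region partition onto alignment columns
#'
#' Maps each region of the reference partition through the reference row's
#' ungapped-to-aligned coordinate map; a region's column set is the
#' contiguous span from its first to its last base's column, so gap columns
#' inside a region belong to that region.
#'
#' @param alignment An `alignment_matrix`.
#' @param reference_id Row id of the reference genome.
#' @param partition The reference genome's `region_partition` (the reference
#'   row's ungapped sequence must be the canonicalized genome).
#' @return Named list of 0-based column index vectors for `LSC`, `IRa`,
#'   `SSC`, `IRb`.
#' @export
region_column_sets <- function(alignment, reference_id, partition) {
  if (!(reference_id %in% alignment$ids)) {
    stop("reference id '", reference_id, "' not in alignment", call. = FALSE)
  }
  map <- ungapped_to_columns(alignment$mat[reference_id, ])
  if (length(map) != partition$genome_length) {
    stop("reference row ungapped length (", length(map),
         ") != partition genome length (", partition$genome_length, ")",
         call. = FALSE)
  }
  region_cols <- function(iv) {
    lo <- map[iv[1L] + 1L]
    hi <- map[iv[2L]]
    seq.int(lo, hi)
  }
  list(LSC = region_cols(partition$lsc), IRa = region_cols(partition$ira),
       SSC = region_cols(partition$ssc), IRb = region_cols(partition$irb))
}

#' Region-wise divergence summary table
#'
#' @param alignment An `alignment_matrix`.
#' @param reference_id Reference row id.
#' @param partition The reference genome's `region_partition`.
#' @return A data.frame with one row per region (LSC, SSC, IR from the IRa
#'   span) plus the complete alignment: raw column count, analyzed sites,
#'   variable sites, parsimony-informative sites and nucleotide diversity.
#' @export
region_stats_table <- function(alignment, reference_id, partition) {
  sets <- region_column_sets(alignment, reference_id, partition)
  pick <- list(LSC = sets$LSC, SSC = sets$SSC, IR = sets$IRa,
               `Complete` = NULL)
  rows <- lapply(names(pick), function(nm) {
    st <- diversity_stats(alignment, pick[[nm]])
    data.frame(region = nm, raw_columns = st$raw_columns, sites = st$sites,
               S = st$S, PI = st$PI, pi = st$pi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance report table (p-distance upper triangle, counts lower)
#'
#' @param dm A `distance_matrix`.
#' @return A data.frame with taxon rows: p-distances (4 decimals) above the
#'   diagonal, nucleotide-difference counts below.
#' @export
distance_report <- function(dm) {
  n <- length(dm$ids)
  cells <- matrix("", n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) cells[i, j] <- formatC(dm$p_distance[i, j], format = "f",
                                        digits = 4L)
      if (i > j) cells[i, j] <- as.character(dm$n_diff[i, j])
    }
  }
  out <- data.frame(taxon = dm$ids, cells, stringsAsFactors = FALSE)
  names(out) <- c("taxon", dm$ids)
  out
}
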