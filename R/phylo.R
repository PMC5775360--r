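# Desk-scale phylogeny stage: neighbor-joining on p-distances, Fitch
# parsimony scoring of a fixed topology, and Robinson-Foulds comparison.
# These delegate to ape/phangorn behind the interfaces the pipeline uses.

#' Neighbor-joining tree from a distance matrix
#'
#' @param dm A `distance_matrix` (see [distance_matrix()]) or a plain
#'   symmetric numeric matrix with dimnames.
#' @return An unrooted `phylo` tree with NJ branch lengths.
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "distance_matrix")) dm$p_distance else dm
  if (nrow(m) < 3L) stop("need >= 3 taxa for neighbor joining", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite distances", call. = FALSE)
  # deterministic tie-break: fix taxon order by label
  ord <- order(rownames(m))
  ape::nj(m[ord, ord])
}

#' Fitch parsimony score of a tree given an alignment
#'
#' Minimum substitution count by Fitch's algorithm, summed over the analyzed
#' (gap/N-free) columns.
#'
#' @param tree A `phylo` tree whose tip labels equal the alignment ids.
#' @param alignment An `alignment_matrix`.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, alignment) {
  if (!setequal(tree$tip.label, alignment$ids)) {
    stop("tree tip labels do not match alignment ids", call. = FALSE)
  }
  mat <- clean_mat(alignment)
  analyzed <- colSums(mat == "-" | mat == "N") == 0L
  m <- mat[, analyzed, drop = FALSE]
  if (ncol(m) == 0L) return(0L)
  dat <- phangorn::phyDat(m, type = "DNA")
  as.integer(phangorn::fitch(tree, dat))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  as.integer(phangorn::RF.dist(t1, t2))
}
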