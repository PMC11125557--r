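#' Neighbor-joining lineage tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining on the complete cell + bulk
#' distance matrix, followed by rerooting at the bulk (see
#' [reroot_at_bulk()]).
#'
#' @param dist a `cell_dist` object from [compute_distances()] or a
#'   complete symmetric labelled matrix.
#' @param reroot reroot so the bulk becomes the outgroup root
#'   (default `TRUE`; ignored when no `bulk` taxon is present).
#' @return a `phylo` tree.
#' @export
nj_tree <- function(dist, reroot = TRUE) {
  m <- if (inherits(dist, "cell_dist")) dist$matrix else as.matrix(dist)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("distance matrix is incomplete: missing entry (%s, %s)",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  tree <- ape::nj(m)
  if (reroot && "bulk" %in% tree$tip.label) tree <- reroot_at_bulk(tree)
  tree
}

#' Reroot a lineage tree at the bulk taxon
#'
#' Places the root on the bulk's pendant edge so the bulk represents the
#' non-mutated state; the bipartitions over the cell leaves are unchanged
#' and the operation is idempotent.
#'
#' @param tree a `phylo` containing a tip labelled `"bulk"`.
#' @return the rerooted `phylo`.
#' @export
reroot_at_bulk <- function(tree) {
  if (!"bulk" %in% tree$tip.label) stop("tree has no 'bulk' tip")
  ape::root(tree, outgroup = "bulk", resolve.root = TRUE)
}

#' Site-bootstrap lineage trees
#'
#' Resamples the selected sites uniformly with replacement, re-aggregates
#' the per-site distance matrices (the coverage masks travel with the
#' sites, so the per-pair denominators are recomputed per resample) and
#' reconstructs one neighbor-joining tree per resample.
#'
#' @param dist a `cell_dist` object from [compute_distances()].
#' @param n_boot number of bootstrap trees.
#' @param seed optional seed.
#' @return a `multiPhylo` list of rerooted trees.
#' @export
bootstrap_trees <- function(dist, n_boot = 100, seed = NULL) {
  if (!inherits(dist, "cell_dist")) stop("need a cell_dist object")
  n_sites <- length(dist$site_matrices)
  if (n_sites == 0) stop("no sites to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    m <- suppressWarnings(
      aggregate_distances(dist$site_matrices[idx], labels = dist$labels))
    if (any(is.na(m))) {
      # a pathological resample can leave a pair undefined even after
      # imputation (all-NA rows); fall back to the full-data matrix entry
      m[is.na(m)] <- dist$matrix[is.na(m)]
    }
    trees[[b]] <- nj_tree(m)
  }
  class(trees) <- "multiPhylo"
  trees
}
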