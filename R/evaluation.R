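# Nontrivial bipartitions of a tree over its cell leaf set. The bulk tip
# (if any) is removed first so trees with and without bulk compare
# consistently. Returns a list: `labels` (sorted leaf labels) and `splits`,
# a logical matrix with one row per internal edge (canonical orientation:
# first leaf FALSE).
cell_bipartitions <- function(tree, drop_bulk = TRUE, nontrivial = TRUE) {
  if (drop_bulk && "bulk" %in% tree$tip.label && length(tree$tip.label) > 3) {
    tree <- ape::drop.tip(tree, "bulk")
  }
  tree <- ape::unroot(tree)
  labels <- sort(tree$tip.label)
  n <- length(labels)
  ntip <- length(tree$tip.label)
  # leaves below each node, accumulated children-first
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- match(tree$tip.label[i], labels)
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  internal <- which(tree$edge[, 2] > ntip)
  splits <- matrix(FALSE, 0, n)
  if (length(internal) > 0) {
    splits <- t(vapply(internal, function(e) {
      v <- rep(FALSE, n)
      v[desc[[tree$edge[e, 2]]]] <- TRUE
      if (v[1]) v <- !v
      v
    }, logical(n)))
  }
  if (nontrivial) {
    side <- pmin(rowSums(splits), n - rowSums(splits))
    splits <- splits[side >= 2, , drop = FALSE]
  }
  splits <- unique(splits)
  list(labels = labels, splits = splits)
}

split_keys <- function(splits) {
  if (nrow(splits) == 0) return(character(0))
  apply(splits, 1, function(v) paste(as.integer(v), collapse = ""))
}

#' Robinson-Foulds similarity between two trees
#'
#' One minus the normalized Robinson-Foulds distance: the number of
#' nontrivial bipartitions present in exactly one tree, divided by the
#' total number of nontrivial (internal) edges of both trees. Identical
#' topologies score 1; trees sharing no nontrivial bipartition score 0.
#' Bipartitions are computed over the cell leaves after removing the bulk
#' tip, so trees with and without bulk compare consistently.
#'
#' @param tree1,tree2 `phylo` trees over the same leaf set.
#' @return similarity in `[0, 1]`.
#' @export
rf_similarity <- function(tree1, tree2) {
  b1 <- cell_bipartitions(tree1)
  b2 <- cell_bipartitions(tree2)
  if (!identical(b1$labels, b2$labels)) {
    stop("trees have different leaf sets")
  }
  k1 <- split_keys(b1$splits)
  k2 <- split_keys(b2$splits)
  ib <- length(k1) + length(k2)
  if (ib == 0) return(1)
  rf <- sum(!k1 %in% k2) + sum(!k2 %in% k1)
  1 - rf / ib
}

# transfer distance between a bipartition and every edge of a bootstrap
# tree: min over edges (trivial ones included) of the bipartition Hamming
# distance, taking the smaller orientation
min_transfer_distance <- function(split, boot_splits, n) {
  d <- Inf
  for (i in seq_len(nrow(boot_splits))) {
    h <- sum(split != boot_splits[i, ])
    d <- min(d, h, n - h)
  }
  d
}

# all splits of a tree including the trivial single-leaf ones
all_splits_with_trivial <- function(tree) {
  bp <- cell_bipartitions(tree, nontrivial = FALSE)
  n <- length(bp$labels)
  trivial <- diag(n) > 0
  # canonical orientation: flip rows whose first entry is TRUE
  trivial <- t(apply(trivial, 1, function(v) if (v[1]) !v else v))
  list(labels = bp$labels, splits = rbind(bp$splits, trivial))
}

#' Transfer bootstrap expectation supports
#'
#' For every nontrivial edge `b` of the reference tree the TBE support is
#' `1 - mean(delta_T / (p - 1))` over the bootstrap trees `T`, where
#' `delta_T` is the minimum transfer distance (number of leaf removals,
#' computed as the minimum bipartition Hamming distance over all of `T`'s
#' edges) and `p` is the size of `b`'s lighter side. A support of 1 means
#' the edge is in every bootstrap tree; 0 means it appears at random.
#'
#' @param ref_tree the reference `phylo` topology.
#' @param boot_trees a list / `multiPhylo` of bootstrap trees over the
#'   same leaf set.
#' @return a tibble with one row per internal edge: `edge` (id), `clade`
#'   (label string of the lighter side), `p` (lighter-side size) and
#'   `support`.
#' @export
tbe_supports <- function(ref_tree, boot_trees) {
  if (length(boot_trees) == 0) stop("empty bootstrap set")
  rb <- cell_bipartitions(ref_tree)
  n <- length(rb$labels)
  boots <- lapply(boot_trees, function(t) {
    bs <- all_splits_with_trivial(t)
    if (!identical(bs$labels, rb$labels)) {
      stop("bootstrap tree leaf set differs from the reference")
    }
    bs$splits
  })
  rows <- lapply(seq_len(nrow(rb$splits)), function(i) {
    split <- rb$splits[i, ]
    p <- min(sum(split), n - sum(split))
    deltas <- vapply(boots, function(bs) {
      min_transfer_distance(split, bs, n)
    }, numeric(1))
    side <- if (sum(split) <= n - sum(split)) split else !split
    tibble::tibble(edge = i,
                   clade = paste(rb$labels[side], collapse = ","),
                   p = p,
                   support = 1 - mean(deltas / (p - 1)))
  })
  dplyr::bind_rows(rows)
}

#' Annotate a reference tree with TBE supports as node labels
#'
#' @param ref_tree the reference `phylo`.
#' @param supports a tibble from [tbe_supports()] (rows follow the
#'   internal-edge order of `cell_bipartitions`).
#' @param digits label precision.
#' @return the tree with supports as internal node labels.
#' @export
project_supports <- function(ref_tree, supports, digits = 2) {
  work <- ref_tree
  drop_bulk <- "bulk" %in% work$tip.label && length(work$tip.label) > 3
  bp <- cell_bipartitions(work)
  keys <- split_keys(bp$splits)
  sup_by_key <- setNames(supports$support, keys[supports$edge])
  ntip <- length(work$tip.label)
  labels <- rep("", work$Nnode)
  # recompute each internal node's split on the cell leaf set
  cell_labels <- bp$labels
  desc <- node_leaf_sets(work)
  for (nd in seq_len(work$Nnode)) {
    node <- ntip + nd
    leaves <- work$tip.label[desc[[node]]]
    leaves <- setdiff(leaves, "bulk")
    v <- rep(FALSE, length(cell_labels))
    v[match(leaves, cell_labels)] <- TRUE
    if (length(cell_labels) == 0 || length(leaves) == 0) next
    if (v[1]) v <- !v
    key <- paste(as.integer(v), collapse = "")
    if (key %in% names(sup_by_key) && !is.na(sup_by_key[[key]])) {
      labels[nd] <- formatC(sup_by_key[[key]], format = "f", digits = digits)
    }
  }
  work$node.label <- labels
  work
}

# tip index sets below every node of a phylo
node_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}
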