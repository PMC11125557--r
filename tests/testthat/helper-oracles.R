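# Independent brute-force oracles. These re-derive quantities from first
# principles (exhaustive enumeration) and deliberately avoid the package's
# computational paths.

# ---- amplification-history enumeration -------------------------------------

# grow a nested-list tree (leaf = 1L) by splitting each leaf in turn
oracle_split_leaves <- function(tr) {
  if (!is.list(tr)) return(list(list(1L, 1L)))
  out <- list()
  for (sub in oracle_split_leaves(tr[[1]])) out <- c(out, list(list(sub, tr[[2]])))
  for (sub in oracle_split_leaves(tr[[2]])) out <- c(out, list(list(tr[[1]], sub)))
  out
}

# all draw-copy histories growing a forest (list of trees) to n total leaves;
# every history is equally likely under the urn
oracle_histories <- function(n_init, n_final) {
  forests <- list(replicate(n_init, 1L, simplify = FALSE))
  n <- n_init
  while (n < n_final) {
    nxt <- list()
    for (f in forests) {
      for (ti in seq_along(f)) {
        for (sub in oracle_split_leaves(f[[ti]])) {
          g <- f
          g[[ti]] <- sub
          nxt <- c(nxt, list(g))
        }
      }
    }
    forests <- nxt
    n <- n + 1
  }
  forests
}

oracle_tree_sizes <- function(tr) {
  if (!is.list(tr)) return(1L)
  l <- oracle_tree_sizes(tr[[1]])
  r <- oracle_tree_sizes(tr[[2]])
  c(l[1] + r[1], l, r)
}

oracle_leaf_count <- function(tr) oracle_tree_sizes(tr)[1]

# Exhaustive configuration distribution under the urn model with exactly one
# amplification error placed uniformly on one of the E edges (root edges
# included) of a uniformly drawn history; f3 uniform over the Hamming-1
# neighbours of the erroneous tree's allele. Returns the aggregated tibble.
oracle_config_dist_A1 <- function(genotype, d1, d2, L) {
  alive <- which(c(d1, d2) == 0)
  hists <- oracle_histories(length(alive), L)
  E <- if (length(alive) == 2) 2 * L - 2 else 2 * L - 1
  den <- 3 * nchar(genotype[1])
  rows <- list()
  for (f in hists) {
    for (ti in seq_along(f)) {
      sizes <- oracle_tree_sizes(f[[ti]]) # every edge incl. the root edge
      allele <- alive[ti]
      origin <- genotype[allele]
      nb <- lineagedist:::hamming1_neighbours(origin)
      n_tree <- vapply(f, oracle_leaf_count, 0L)
      for (k in sizes) {
        for (f3 in nb) {
          n <- c(0L, 0L)
          n[alive] <- n_tree
          n[allele] <- n[allele] - k
          rows[[length(rows) + 1]] <- data.frame(
            f3 = f3, n1 = n[1], n2 = n[2], n3 = k,
            prob = 1 / length(hists) / E / den)
        }
      }
    }
  }
  agg <- aggregate(prob ~ f3 + n1 + n2 + n3, data = do.call(rbind, rows), sum)
  agg[order(agg$n1, agg$n3, agg$f3), ]
}

# same, A = 0: only the allele split matters
oracle_config_dist_A0 <- function(d1, d2, L) {
  alive <- which(c(d1, d2) == 0)
  hists <- oracle_histories(length(alive), L)
  rows <- lapply(hists, function(f) {
    n <- c(0L, 0L)
    n[alive] <- vapply(f, oracle_leaf_count, 0L)
    data.frame(n1 = n[1], n2 = n[2], n3 = 0L, prob = 1 / length(hists))
  })
  agg <- aggregate(prob ~ n1 + n2 + n3, data = do.call(rbind, rows), sum)
  agg[order(agg$n1), ]
}

# ---- read-assignment enumeration -------------------------------------------

oracle_reads_likelihood <- function(bases, error_probs, fragments, counts) {
  L <- nrow(bases)
  assign <- expand.grid(rep(list(1:3), L))
  ok <- apply(assign, 1, function(a) all(tabulate(a, 3) == counts))
  vals <- apply(assign[ok, , drop = FALSE], 1, function(a) {
    prod(vapply(seq_len(L), function(l) {
      single_read_likelihood(bases[l, ], fragments[a[l]], error_probs[l, ])
    }, 0))
  })
  mean(vals)
}

# ---- pairwise posterior by 2^C enumeration ---------------------------------

oracle_pair_posterior <- function(site, c1, c2, params) {
  C <- length(site$cells)
  types <- enumerate_mutation_types(site$bulk, cand_index = 1)
  K <- length(types)
  lik <- function(ci, g, z) {
    obs <- site$cells[[ci]]
    X <- if (g == 0) site$bulk else types[[z]]
    if (is.null(obs)) 1 else {
      cell_genotype_likelihood(obs$bases, obs$error_probs, X, params)
    }
  }
  joint <- matrix(0, 2, 2)
  for (z in seq_len(K)) {
    for (s in 0:(2^C - 1)) {
      g <- as.integer(intToBits(s))[1:C]
      p <- (1 / K) * mutation_count_weight(sum(g), C, params$a, params$b) *
        prod(vapply(1:C, function(ci) lik(ci, g[ci], z), 0))
      joint[g[c1] + 1, g[c2] + 1] <- joint[g[c1] + 1, g[c2] + 1] + p
    }
  }
  joint / sum(joint)
}

oracle_sites_loglik <- function(sites, params) {
  total <- 0
  for (i in seq_len(nrow(sites))) {
    site <- sites$site[[i]]
    C <- length(site$cells)
    types <- enumerate_mutation_types(site$bulk, cand_index = 1)
    K <- length(types)
    s <- 0
    for (z in seq_len(K)) {
      for (st in 0:(2^C - 1)) {
        g <- as.integer(intToBits(st))[1:C]
        p <- (1 / K) * mutation_count_weight(sum(g), C, params$a, params$b)
        for (ci in 1:C) {
          obs <- site$cells[[ci]]
          X <- if (g[ci] == 0) site$bulk else types[[z]]
          if (!is.null(obs)) {
            p <- p * cell_genotype_likelihood(obs$bases, obs$error_probs,
                                              X, params)
          }
        }
        s <- s + p
      }
    }
    total <- total + log(s)
  }
  total
}

# ---- transfer distance by leaf removal -------------------------------------

# minimum number of leaves whose removal makes `split` (logical over
# `labels`) match an edge bipartition (trivial ones included) of `tree`
oracle_transfer_distance <- function(split, tree, labels) {
  n <- length(labels)
  tree_splits_restricted <- function(keep) {
    kept <- labels[keep]
    tr <- tree
    drop <- setdiff(tree$tip.label, c(kept, character(0)))
    drop <- setdiff(drop, "bulk")
    if (length(kept) < 2) return(NULL)
    if (length(drop) > 0) tr <- ape::drop.tip(tr, drop)
    bp <- lineagedist:::cell_bipartitions(tr, nontrivial = FALSE)
    # reorder to the kept labels
    keys <- apply(bp$splits, 1, function(v) {
      v <- v[match(sort(kept), bp$labels)]
      if (v[1]) v <- !v
      paste(as.integer(v), collapse = "")
    })
    keys
  }
  for (k in 0:(n - 2)) {
    for (rem in utils::combn(n, k, simplify = FALSE)) {
      keep <- setdiff(seq_len(n), rem)
      v <- split[keep][order(labels[keep])]
      if (sum(v) == 0 || sum(!v) == 0) return(k) # became trivial: matches
      if (sum(v) == 1 || sum(!v) == 1) return(k) # a pendant-edge split
      if (v[1]) v <- !v
      key <- paste(as.integer(v), collapse = "")
      if (key %in% tree_splits_restricted(keep)) return(k)
    }
  }
  n - 2
}

# ---- misc -------------------------------------------------------------------

make_cell_obs <- function(L, P = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (L == 0) return(NULL)
  list(bases = matrix(sample(c("A", "C", "G", "T"), L * P, TRUE), L, P),
       error_probs = matrix(runif(L * P, 1e-3, 0.05), L, P))
}

make_site <- function(cell_Ls, kind = "singleton", bulk = NULL, seed = 1) {
  set.seed(seed)
  P <- if (kind == "singleton") 1 else 2
  if (is.null(bulk)) bulk <- if (P == 1) c("A", "A") else c("AG", "AT")
  list(kind = kind, positions = seq_len(P), bulk = bulk,
       cells = lapply(cell_Ls, make_cell_obs, P = P))
}
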