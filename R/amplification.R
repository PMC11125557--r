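#' Prior probability of an allelic-dropout state
#'
#' The two alleles of a cell drop out independently with the same
#' probability, so the prior over the four dropout states factorises as
#' `p_ado^(d1 + d2) * (1 - p_ado)^(2 - d1 - d2)`.
#'
#' @param d1,d2 binary dropout indicators for allele 1 and allele 2.
#' @param p_ado allelic dropout probability.
#' @return the prior probability of the state `(d1, d2)`.
#' @examples
#' ado_prior(0, 0, 0.1) # 0.81
#' @export
ado_prior <- function(d1, d2, p_ado) {
  stopifnot(d1 %in% c(0, 1), d2 %in% c(0, 1))
  stopifnot_prob(p_ado, "p_ado")
  p_ado^(d1 + d2) * (1 - p_ado)^(2 - d1 - d2)
}

#' Total number of amplification-tree edges
#'
#' Counts the edges of the one or two amplification trees that can carry an
#' amplification error, given the dropout state and the observed coverage.
#' Each tree contributes its internal edges plus one incoming root edge that
#' accounts for subsampling during sequencing: `2L - 2` edges with no
#' dropout, `2L - 1` with exactly one dropout, and 0 when both alleles are
#' lost.
#'
#' @param d1,d2 binary dropout indicators.
#' @param L read coverage (total number of fragments).
#' @return integer edge count.
#' @export
edge_count <- function(d1, d2, L) {
  stopifnot(d1 %in% c(0, 1), d2 %in% c(0, 1))
  if (d1 == 1 && d2 == 1) return(0L)
  if (L < 1) stop("L must be >= 1 unless both alleles are dropped")
  if (d1 == 0 && d2 == 0) 2L * L - 2L else 2L * L - 1L
}

#' Probability of the number of amplification errors
#'
#' A Binomial distribution over the amplification-tree edges, truncated to
#' at most one error without renormalisation: the neglected mass is the
#' probability of two or more errors, which is negligible for realistic
#' amplification error rates.
#'
#' @param A number of amplification errors (0 or 1).
#' @param E total number of amplification-tree edges (see [edge_count()]).
#' @param p_ae per-edge amplification error probability.
#' @return `dbinom(A, E, p_ae)`.
#' @export
ae_count_prob <- function(A, E, p_ae) {
  if (!A %in% c(0, 1)) {
    stop("the model truncates the amplification error count to {0, 1}")
  }
  stopifnot_prob(p_ae, "p_ae")
  stats::dbinom(A, E, p_ae)
}

#' Number of order-labelled amplification-tree topologies
#'
#' An amplification tree records the genealogy of the fragments amplified
#' from one original allele molecule: each draw-copy step of the urn splits
#' one current fragment into two, and the splits are labelled by their time
#' order. Growing from 1 to `n` fragments offers `2, 3, ..., n - 1` choices,
#' so there are `(n - 1)!` distinct order-labelled topologies. The
#' `"enumerate"` method constructs every draw history explicitly and is the
#' reference the closed form is validated against.
#'
#' @param n number of fragments (leaves of the amplification tree).
#' @param method `"closed_form"` (default) or `"enumerate"`.
#' @return the topology count `C(n)`.
#' @examples
#' tree_count(4) # 6
#' @export
tree_count <- function(n, method = c("closed_form", "enumerate")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (method == "closed_form") return(factorial(n - 1))
  length(enumerate_amplification_trees(n))
}

#' Number of k-edges across all n-fragment amplification trees
#'
#' Counts, over all `C(n)` order-labelled topologies, the edges whose
#' below-edge subtree contains exactly `k` fragments. The incoming root edge
#' is included, so `k = n` contributes one edge per topology and the counts
#' sum to `C(n) * (2n - 1)`. The closed-form path uses the recurrence
#' `f(n, k) = (n - 1 - k) f(n-1, k) + (k - 1) f(n-1, k-1)` (with
#' `f(n, 1) = n (n-1)!`), validated against exhaustive history enumeration.
#'
#' @inheritParams tree_count
#' @param k subtree size, `1 <= k <= n`.
#' @return the edge count `C(n, k)`.
#' @export
subtree_edge_count <- function(n, k, method = c("closed_form", "enumerate")) {
  method <- match.arg(method)
  if (k < 1 || k > n) stop("k must be in [1, n]")
  if (method == "closed_form") {
    w <- subtree_weight_matrix(n)
    return(round(w[n + 1, k + 1] * factorial(n - 1)))
  }
  trees <- enumerate_amplification_trees(n)
  sum(vapply(trees, function(tr) sum(amplification_node_sizes(tr) == k), 0L))
}

# w[n+1, k+1] = C(n, k) / C(n): expected number of k-edges (root edge
# included) in a uniformly drawn order-labelled amplification tree.
subtree_weight_matrix <- function(n_max) {
  key <- as.character(n_max)
  cached <- .ld_cache$w_matrix
  if (!is.null(cached) && nrow(cached) >= n_max + 1) return(cached)
  n_max <- max(n_max, 8L)
  w <- matrix(0, n_max + 1, n_max + 1)
  w[2, 2] <- 1 # n = 1: the root edge
  for (n in 2:n_max) {
    w[n + 1, 2] <- n
    for (k in 2:n) {
      w[n + 1, k + 1] <- ((n - 1 - k) * w[n, k + 1] +
                          (k - 1) * w[n, k]) / (n - 1)
    }
  }
  .ld_cache$w_matrix <- w
  w
}

# Exhaustive enumeration of order-labelled amplification trees (draw-copy
# histories). A tree is a nested list; a leaf is the atom 1L. Every distinct
# history is kept as a distinct topology, matching the order labelling.
enumerate_amplification_trees <- function(n) {
  grow <- function(tr) {
    if (!is.list(tr)) return(list(list(1L, 1L)))
    out <- list()
    for (sub in grow(tr[[1]])) out <- c(out, list(list(sub, tr[[2]])))
    for (sub in grow(tr[[2]])) out <- c(out, list(list(tr[[1]], sub)))
    out
  }
  trees <- list(1L)
  if (n == 1) return(trees)
  for (i in seq_len(n - 1)) {
    trees <- unlist(lapply(trees, grow), recursive = FALSE)
  }
  trees
}

# subtree sizes of every edge of an amplification tree, the root edge first
amplification_node_sizes <- function(tr) {
  if (!is.list(tr)) return(1L)
  l <- amplification_node_sizes(tr[[1]])
  r <- amplification_node_sizes(tr[[2]])
  c(l[1] + r[1], l, r)
}

#' Enumerate fragment-type and count configurations with their probabilities
#'
#' Given the cell genotype, the dropout state, the number of amplification
#' errors and the coverage, lists every reachable fragment configuration
#' `(F, N)` with its probability under the urn model. The probability is the
#' product of (i) the partition factor (uniform `1/(L-1)` over the
#' Beta-Binomial allele splits when neither allele dropped, a single
#' partition otherwise), (ii) the topology factor
#' `C(n_err_tree, n3) / (C(n_err_tree) * E)` marginalizing the
#' amplification-tree topologies and the erroneous edge, and (iii) the
#' error-type factor (1/3 per specific erroneous fragment at singleton
#' sites, 1/6 at paired sites). Probabilities sum to 1 for every valid
#' branch.
#'
#' @param genotype character vector of length 2: the two allele fragment
#'   strings (1 base for singleton sites, 2 bases for paired sites).
#' @param d1,d2 binary dropout indicators.
#' @param A number of amplification errors (0 or 1).
#' @param L coverage (total fragment count).
#' @param kind `"singleton"` or `"paired"`; defaults to the fragment width.
#' @return a tibble with columns `f1`, `f2`, `f3`, `n1`, `n2`, `n3`, `prob`.
#'   `f3` is `NA` when no error occurred. An empty tibble marks a
#'   zero-probability branch (e.g. both alleles dropped with `L > 0`).
#' @export
enumerate_configs <- function(genotype, d1, d2, A, L,
                              kind = c("auto", "singleton", "paired")) {
  kind <- match.arg(kind)
  stopifnot(length(genotype) == 2, d1 %in% c(0, 1), d2 %in% c(0, 1))
  if (!A %in% c(0, 1)) stop("the model truncates A to {0, 1}")
  width <- nchar(genotype[1])
  if (kind == "auto") kind <- if (width == 1) "singleton" else "paired"
  den <- 3 * width
  f1 <- genotype[1]
  f2 <- genotype[2]
  empty <- tibble::tibble(f1 = character(), f2 = character(),
                          f3 = character(), n1 = integer(), n2 = integer(),
                          n3 = integer(), prob = numeric())
  if ((d1 == 1 && d2 == 1) || L < 1) return(empty)
  rows <- list()
  add <- function(f3, n1, n2, n3, prob) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      f1 = f1, f2 = f2, f3 = f3, n1 = as.integer(n1), n2 = as.integer(n2),
      n3 = as.integer(n3), prob = prob)
  }
  w <- subtree_weight_matrix(L)
  if (A == 0) {
    if (d1 == 1) {
      add(NA_character_, 0, L, 0, 1)
    } else if (d2 == 1) {
      add(NA_character_, L, 0, 0, 1)
    } else {
      if (L >= 2) {
        for (j in seq_len(L - 1)) add(NA_character_, j, L - j, 0, 1 / (L - 1))
      }
    }
  } else {
    E <- edge_count(d1, d2, L)
    if (d1 == 1 || d2 == 1) {
      origin <- if (d1 == 1) f2 else f1
      for (f3 in hamming1_neighbours(origin)) {
        for (k in seq_len(L)) {
          p <- w[L + 1, k + 1] / E / den
          if (d1 == 1) add(f3, 0, L - k, k, p) else add(f3, L - k, 0, k, p)
        }
      }
    } else if (L >= 2) {
      for (j in seq_len(L - 1)) {
        part <- 1 / (L - 1)
        for (f3 in hamming1_neighbours(f1)) { # error in the first tree
          for (k in seq_len(j)) {
            add(f3, j - k, L - j, k, part * w[j + 1, k + 1] / E / den)
          }
        }
        for (f3 in hamming1_neighbours(f2)) { # error in the second tree
          for (k in seq_len(L - j)) {
            add(f3, j, L - j - k, k, part * w[L - j + 1, k + 1] / E / den)
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$f1, .data$f2, .data$f3,
                    .data$n1, .data$n2, .data$n3),
    prob = sum(.data$prob), .groups = "drop")
  dplyr::arrange(out, .data$n1, .data$n3, .data$f3)
}
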