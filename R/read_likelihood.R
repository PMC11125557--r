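#' Likelihood of a single read given its originating fragment
#'
#' Per covered position the read matches its fragment with probability
#' `1 - q` and shows any specific other nucleotide with probability `q / 3`,
#' where `q` is the base-calling error probability. At paired sites the two
#' positions contribute independent factors; positions the read does not
#' cover (NA base) contribute a factor of 1.
#'
#' @param bases character vector of observed bases at the site position(s)
#'   (`NA` for an uncovered position).
#' @param fragment fragment string (1 or 2 characters).
#' @param error_probs base-calling error probabilities, one per position.
#' @return the read likelihood.
#' @examples
#' single_read_likelihood("A", "A", 0.01)           # 0.99
#' single_read_likelihood(c("A", "G"), "AG", c(0.01, 0.02))
#' @export
single_read_likelihood <- function(bases, fragment, error_probs) {
  frag <- strsplit(fragment, "")[[1]]
  stopifnot(length(bases) == length(frag),
            length(error_probs) == length(frag))
  p <- 1
  for (i in seq_along(frag)) {
    if (is.na(bases[i])) next
    p <- p * if (bases[i] == frag[i]) 1 - error_probs[i] else error_probs[i] / 3
  }
  p
}

# Per-read likelihoods under a set of fragment strings.
# bases: L x P character matrix (NA = uncovered), q: L x P error probs.
# Returns L x length(frags) matrix.
frag_lik_matrix <- function(bases, q, frags) {
  L <- nrow(bases)
  P <- ncol(bases)
  out <- matrix(1, L, length(frags))
  for (fi in seq_along(frags)) {
    fr <- strsplit(frags[fi], "")[[1]]
    for (j in seq_len(P)) {
      covered <- !is.na(bases[, j])
      match <- covered & bases[, j] == fr[j]
      fac <- rep(1, L)
      fac[match] <- 1 - q[match, j]
      fac[covered & !match] <- q[covered & !match, j] / 3
      out[, fi] <- out[, fi] * fac
    }
  }
  colnames(out) <- frags
  out
}

#' Likelihood of a cell's read multiset given a fragment configuration
#'
#' Computes `P(R | F, N, Q)` under the assumption that each read was
#' sequenced from a uniformly chosen fragment: the sum over read-to-fragment
#' assignments consistent with the counts `N`, divided by the multinomial
#' coefficient, evaluated by a dynamic program over
#' (reads introduced, fragment-1 uses, fragment-3 uses) in `O(L^3)`.
#'
#' @param bases L x P character matrix of observed read bases at the site
#'   position(s).
#' @param error_probs L x P matrix of base-calling error probabilities.
#' @param fragments character vector `(f1, f2, f3)`; `f3` may be `NA` when
#'   `N[3] == 0`.
#' @param counts integer vector `(n1, n2, n3)` summing to the read count.
#' @return the likelihood of the read multiset.
#' @export
reads_likelihood_dp <- function(bases, error_probs, fragments, counts) {
  bases <- as.matrix(bases)
  error_probs <- as.matrix(error_probs)
  L <- nrow(bases)
  if (sum(counts) != L) {
    stop(sprintf("counts sum to %d but there are %d reads", sum(counts), L))
  }
  if (is.na(fragments[3]) && counts[3] > 0) {
    stop("n3 > 0 requires an erroneous fragment type f3")
  }
  frags <- fragments
  frags[is.na(frags)] <- fragments[1] # placeholder column, never selected
  P <- frag_lik_matrix(bases, error_probs, frags)
  if (is.na(fragments[3])) P[, 3] <- 0
  D <- cpp_read_dp(P)
  D[counts[1] + 1, counts[3] + 1]
}

# All fragment strings of the site width, in a fixed column order:
# singletons A C G T; paired sites the 16 dinucleotides AA, AC, ..., TT.
all_fragments <- function(width) {
  if (width == 1) return(NUC)
  as.vector(t(outer(NUC, NUC, paste0)))
}

# Build the per-cell, per-genotype branch-sum cache of one site.
# site: a site observation (see select_sites()); params only supplies the
# hyperparameter alpha for the mutation-type prior. The cache holds
# everything that does not depend on (p_ado, p_ae).
build_site_cache <- function(site, alpha = NULL) {
  B <- site$bulk
  width <- nchar(B[1])
  kind <- if (width == 1) "singleton" else "paired"
  types <- enumerate_mutation_types(B, kind = kind, cand_index = 1)
  K <- length(types)
  genos <- c(list(B), types)
  frags <- all_fragments(width)
  col_of <- function(s) match(s, frags)
  C <- length(site$cells)
  S <- array(0, dim = c(C, K + 1, 6))
  Lvec <- integer(C)
  maxL <- max(c(1L, vapply(site$cells, function(x) {
    if (is.null(x)) 0L else nrow(x$bases)
  }, 0L)))
  w <- subtree_weight_matrix(maxL)
  for (ci in seq_len(C)) {
    obs <- site$cells[[ci]]
    L <- if (is.null(obs)) 0L else nrow(obs$bases)
    Lvec[ci] <- L
    if (L == 0) next
    P <- frag_lik_matrix(obs$bases, obs$error_probs, frags)
    for (gi in seq_along(genos)) {
      g <- genos[[gi]]
      nb1 <- vapply(hamming1_neighbours(g[1]), col_of, 0L)
      nb2 <- vapply(hamming1_neighbours(g[2]), col_of, 0L)
      S[ci, gi, ] <- cpp_branch_sums(P, col_of(g[1]), col_of(g[2]),
                                     nb1, nb2, w, 3 * width)
    }
  }
  if (is.null(alpha)) alpha <- rep(1, K)
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  prior <- mutation_type_prior(alpha)
  list(L = Lvec, S = S, prior = prior, types = types, bulk = B, kind = kind)
}

#' Marginal likelihood of one cell's reads under a genotype
#'
#' Marginalizes the allelic-dropout state, the truncated amplification-error
#' count and every fragment configuration: the Bernoulli dropout prior times
#' the Binomial edge-error probability times the urn configuration
#' probability times the read-assignment likelihood, summed over all
#' branches. A cell with no coverage has likelihood 1 under every genotype.
#'
#' @param bases,error_probs the cell's reads at the site (L x P matrices);
#'   `NULL` or zero rows means no coverage.
#' @param genotype character vector of length 2 (allele fragment strings).
#' @param params model parameters from [model_params()].
#' @return the marginal likelihood `P(R_c | X_c, Q_c, L_c, p_ado, p_ae)`.
#' @export
cell_genotype_likelihood <- function(bases, error_probs, genotype, params) {
  if (is.null(bases) || nrow(as.matrix(bases)) == 0) return(1)
  bases <- as.matrix(bases)
  error_probs <- as.matrix(error_probs)
  width <- nchar(genotype[1])
  frags <- all_fragments(width)
  col_of <- function(s) match(s, frags)
  L <- nrow(bases)
  w <- subtree_weight_matrix(L)
  P <- frag_lik_matrix(bases, error_probs, frags)
  nb1 <- vapply(hamming1_neighbours(genotype[1]), col_of, 0L)
  nb2 <- vapply(hamming1_neighbours(genotype[2]), col_of, 0L)
  s <- cpp_branch_sums(P, col_of(genotype[1]), col_of(genotype[2]),
                       nb1, nb2, w, 3 * width)
  cache <- list(L = L, S = array(s, dim = c(1, 1, 6)))
  cpp_lik_matrix(cache, params$p_ado, params$p_ae)[1, 1]
}
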