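#' Model parameters and hyperparameters
#'
#' @param p_ado allelic dropout probability.
#' @param p_ae per-edge amplification error probability.
#' @param alpha concentration parameter(s) of the Dirichlet-Categorical
#'   mutation-type prior; a scalar is recycled (the all-ones default makes
#'   every mutation type equally likely).
#' @param a,b Beta hyperparameters of the mutation probability, which is
#'   integrated out analytically; the default `a = b = 1` is a uniform
#'   prior.
#' @return an object of class `ld_params`.
#' @export
model_params <- function(p_ado = 0.1, p_ae = 1e-3, alpha = 1, a = 1, b = 1) {
  stopifnot_prob(p_ado, "p_ado")
  stopifnot_prob(p_ae, "p_ae")
  if (any(alpha <= 0) || a <= 0 || b <= 0) {
    stop("alpha, a and b must be strictly positive")
  }
  structure(list(p_ado = p_ado, p_ae = p_ae, alpha = alpha, a = a, b = b),
            class = "ld_params")
}

#' @export
print.ld_params <- function(x, ...) {
  cat(sprintf("model parameters: p_ado = %g, p_ae = %g, a = %g, b = %g\n",
              x$p_ado, x$p_ae, x$a, x$b))
  invisible(x)
}

#' Enumerate the possible mutation types at a site
#'
#' Under the infinite sites assumption every mutated cell shares one
#' mutation type `Z`, which differs from the bulk genotype by a single
#' nucleotide at the candidate position. A homozygous singleton bulk
#' `(r, r)` admits the 3 heterozygous types `(r, a)`; a paired bulk
#' `(h1, h2)` admits 6 types, substituting the candidate-position
#' nucleotide of either haplotype by each of its 3 alternatives.
#'
#' @param B character vector of length 2: the bulk haplotype strings.
#' @param kind `"singleton"` or `"paired"` (default: from the string width).
#' @param cand_index position of the candidate site within the haplotype
#'   strings (paired sites only).
#' @return list of genotype character vectors.
#' @examples
#' enumerate_mutation_types(c("A", "A"))        # 3 types
#' enumerate_mutation_types(c("AA", "AT"))      # 6 types
#' @export
enumerate_mutation_types <- function(B, kind = c("auto", "singleton", "paired"),
                                     cand_index = 1) {
  kind <- match.arg(kind)
  width <- nchar(B[1])
  if (kind == "auto") kind <- if (width == 1) "singleton" else "paired"
  if (kind == "singleton") {
    r <- B[1]
    return(lapply(setdiff(NUC, r), function(a) c(r, a)))
  }
  out <- list()
  for (hap in 1:2) {
    ref <- substr(B[hap], cand_index, cand_index)
    for (a in setdiff(NUC, ref)) {
      z <- B
      substr(z[hap], cand_index, cand_index) <- a
      out <- c(out, list(z))
    }
  }
  out
}

#' Prior probability of each mutation type
#'
#' The shared mutation type follows a Dirichlet-Categorical distribution:
#' `P(Z = z) = Beta(sum(alpha), 1) / Beta(alpha_z, 1)`, which reduces to
#' `1 / K` for the all-ones concentration vector.
#'
#' @param alpha concentration vector (one entry per mutation type).
#' @return a probability vector over the types, summing to 1.
#' @export
mutation_type_prior <- function(alpha) {
  exp(lbeta(sum(alpha), 1) - lbeta(alpha, 1))
}

#' Marginal probability of one mutation-status vector with m mutated cells
#'
#' The mutation probability carries a Beta(a, b) prior and is integrated
#' out, so any specific status vector with `m` of `C` cells mutated has
#' probability `Beta(m + a, C - m + b) / Beta(a, b)`.
#'
#' @param m number of mutated cells.
#' @param C total number of cells.
#' @param a,b Beta hyperparameters.
#' @return the probability weight.
#' @export
mutation_count_weight <- function(m, C, a = 1, b = 1) {
  exp(lbeta(m + a, C - m + b) - lbeta(a, b))
}

# Subset-sum polynomial over cells: coefficient T[m + 1] is the sum over all
# size-m subsets of prod(lz[subset]) * prod(lb[complement]). Likelihoods are
# scaled per cell to avoid underflow; returns list(T, logscale). Cells with
# both likelihoods zero (degenerate under the truncated model) carry no
# information and are treated as (1, 1).
subset_sum_poly <- function(lb, lz) {
  n <- length(lb)
  T <- c(1, rep(0, n))
  logscale <- 0
  for (i in seq_len(n)) {
    M <- max(lb[i], lz[i])
    if (M <= 0) {
      b <- 1
      z <- 1
    } else {
      b <- lb[i] / M
      z <- lz[i] / M
      logscale <- logscale + log(M)
    }
    T[2:(i + 1)] <- T[2:(i + 1)] * b + T[1:i] * z
    T[1] <- T[1] * b
  }
  list(T = T, logscale = logscale)
}

# 2x2 joint posterior over (G_c, G_c') from a site cache.
pair_posterior_from_cache <- function(cache, c1, c2, params) {
  C <- length(cache$L)
  lik <- cpp_lik_matrix(cache, params$p_ado, params$p_ae)
  if (all(lik[c1, ] <= 0) || all(lik[c2, ] <= 0)) return(NULL)
  K <- ncol(lik) - 1
  others <- setdiff(seq_len(C), c(c1, c2))
  logj <- matrix(-Inf, 2, 2)
  terms <- array(-Inf, dim = c(K, 2, 2))
  for (z in seq_len(K)) {
    ss <- subset_sum_poly(lik[others, 1], lik[others, z + 1])
    m_other <- seq_along(ss$T) - 1
    for (g1 in 0:1) {
      for (g2 in 0:1) {
        l1 <- lik[c1, if (g1 == 0) 1 else z + 1]
        l2 <- lik[c2, if (g2 == 0) 1 else z + 1]
        wgt <- mutation_count_weight(m_other + g1 + g2, C, params$a, params$b)
        s <- sum(ss$T * wgt) * l1 * l2
        terms[z, g1 + 1, g2 + 1] <-
          log(cache$prior[z]) + log(s) + ss$logscale
      }
    }
  }
  for (g1 in 1:2) for (g2 in 1:2) logj[g1, g2] <- lse(terms[, g1, g2])
  post <- exp(logj - lse(as.vector(logj)))
  dimnames(post) <- list(G_c = c("0", "1"), G_cprime = c("0", "1"))
  post
}

#' Posterior over the mutation statuses of a cell pair at one site
#'
#' Marginalizes the shared mutation type, the mutation statuses of all other
#' cells (a subset-sum dynamic program with the Beta-Binomial count weight)
#' and, inside each per-cell likelihood, the dropout/amplification latent
#' variables. The result is the normalized 2x2 table
#' `P(G_c, G_c' | B, R, Q, L, theta)`.
#'
#' @param site one site observation (an element of the `site` list column
#'   returned by [select_sites()]).
#' @param c1,c2 cell indices.
#' @param params model parameters from [model_params()].
#' @return a 2x2 matrix over `(G_c, G_c') in {0,1}^2`, or `NULL` when
#'   either cell carries no usable coverage at the site.
#' @export
pair_posterior <- function(site, c1, c2, params = model_params()) {
  cache <- build_site_cache(site, alpha = params$alpha)
  pair_posterior_from_cache(cache, c1, c2, params)
}

#' Genotype-difference distance of a cell pair at one site
#'
#' @param posterior a 2x2 pair posterior from [pair_posterior()].
#' @return `P(G_c = 0, G_c' = 1) + P(G_c = 1, G_c' = 0)`, in `[0, 1]`.
#' @export
site_distance <- function(posterior) {
  posterior[1, 2] + posterior[2, 1]
}

# marginal posterior P(G_c = 1) at one site: the distance to the
# non-mutated bulk
bulk_posterior_from_cache <- function(cache, c1, params) {
  C <- length(cache$L)
  lik <- cpp_lik_matrix(cache, params$p_ado, params$p_ae)
  if (all(lik[c1, ] <= 0)) return(NA_real_)
  K <- ncol(lik) - 1
  others <- setdiff(seq_len(C), c1)
  terms <- matrix(-Inf, K, 2)
  for (z in seq_len(K)) {
    ss <- subset_sum_poly(lik[others, 1], lik[others, z + 1])
    m_other <- seq_along(ss$T) - 1
    for (g in 0:1) {
      wgt <- mutation_count_weight(m_other + g, C, params$a, params$b)
      s <- sum(ss$T * wgt) * lik[c1, if (g == 0) 1 else z + 1]
      terms[z, g + 1] <- log(cache$prior[z]) + log(s) + ss$logscale
    }
  }
  lg <- c(lse(terms[, 1]), lse(terms[, 2]))
  exp(lg[2] - lse(lg))
}

#' Distance of a cell to the non-mutated bulk at one site
#'
#' @inheritParams pair_posterior
#' @param c1 cell index.
#' @return the marginal posterior `P(G_c = 1)` at the site.
#' @export
site_bulk_distance <- function(site, c1, params = model_params()) {
  cache <- build_site_cache(site, alpha = params$alpha)
  bulk_posterior_from_cache(cache, c1, params)
}

# Site-associated distance matrix over cells + bulk, plus the coverage mask.
site_distance_matrix <- function(cache, params) {
  C <- length(cache$L)
  lik <- cpp_lik_matrix(cache, params$p_ado, params$p_ae)
  usable <- cache$L > 0 & rowSums(lik) > 0
  M <- matrix(NA_real_, C + 1, C + 1)
  diag(M) <- 0
  for (c1 in seq_len(C)) {
    if (!usable[c1]) next
    for (c2 in seq_len(C)) {
      if (c2 <= c1 || !usable[c2]) next
      post <- pair_posterior_from_cache(cache, c1, c2, params)
      M[c1, c2] <- M[c2, c1] <- site_distance(post)
    }
    M[c1, C + 1] <- M[C + 1, c1] <- bulk_posterior_from_cache(cache, c1, params)
  }
  M[C + 1, C + 1] <- 0
  list(M = M, usable = usable)
}

#' Aggregate per-site distance matrices into one distance matrix
#'
#' The distance between two cells is the mean of their per-site distances
#' over the sites where both have coverage; the distance of a cell to the
#' bulk averages over the sites where the cell has coverage. A pair with no
#' co-covered site is imputed with the mean of the two cells' defined
#' distances (with a warning), because neighbor joining needs a complete
#' matrix.
#'
#' @param site_mats list (or array) of per-site `(C+1) x (C+1)` matrices
#'   with `NA` marking uncovered pairs.
#' @param labels taxon labels (cells, then `"bulk"`).
#' @return a symmetric `(C+1) x (C+1)` matrix with zero diagonal.
#' @export
aggregate_distances <- function(site_mats, labels = NULL) {
  if (is.array(site_mats) && length(dim(site_mats)) == 3) {
    site_mats <- lapply(seq_len(dim(site_mats)[1]),
                        function(i) site_mats[i, , ])
  }
  n <- nrow(site_mats[[1]])
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (M in site_mats) {
    ok <- !is.na(M)
    acc[ok] <- acc[ok] + M[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  diag(out) <- 0
  missing <- which(is.na(out) & upper.tri(out), arr.ind = TRUE)
  if (nrow(missing) > 0) {
    warning(sprintf(
      "%d cell pair(s) share no covered site; imputing with row means",
      nrow(missing)), call. = FALSE)
    for (i in seq_len(nrow(missing))) {
      r <- missing[i, 1]
      s <- missing[i, 2]
      vals <- c(out[r, -r], out[s, -s])
      out[r, s] <- out[s, r] <- mean(vals, na.rm = TRUE)
    }
  }
  if (!is.null(labels)) dimnames(out) <- list(labels, labels)
  out
}

#' Compute the cell-pair distance matrix over all selected sites
#'
#' Runs the per-site posterior model at every site (optionally in parallel;
#' the per-site computations are independent and the reduction is
#' order-invariant, so results do not depend on `jobs`) and aggregates the
#' site-associated matrices into one distance matrix over the cells plus
#' the bulk.
#'
#' @param sites a site set from [select_sites()] or [read_sites()].
#' @param params model parameters from [model_params()].
#' @param jobs number of worker processes for the per-site computations.
#' @return an object of class `cell_dist`: the aggregated matrix, the
#'   per-site matrices, the coverage masks and the site metadata.
#' @export
compute_distances <- function(sites, params = model_params(), jobs = 1) {
  site_list <- sites$site
  C <- attr(sites, "n_cells")
  if (is.null(C) && length(site_list) > 0) {
    C <- length(site_list[[1]]$cells)
  }
  if (length(site_list) == 0) stop("no sites to analyse")
  one <- function(s) {
    cache <- build_site_cache(s, alpha = params$alpha)
    site_distance_matrix(cache, params)
  }
  if (jobs > 1 && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(site_list, one, mc.cores = jobs,
                              mc.preschedule = TRUE)
  } else {
    res <- lapply(site_list, one)
  }
  labels <- c(paste0("cell", seq_len(C)), "bulk")
  mats <- lapply(res, `[[`, "M")
  masks <- do.call(rbind, lapply(res, `[[`, "usable"))
  agg <- aggregate_distances(mats, labels = labels)
  meta <- dplyr::select(sites, -dplyr::any_of("site"))
  structure(list(matrix = agg, site_matrices = mats, coverage = masks,
                 labels = labels, sites = meta, params = params),
            class = "cell_dist")
}

#' @export
print.cell_dist <- function(x, ...) {
  cat(sprintf("cell distance matrix: %d taxa (incl. bulk), %d sites\n",
              nrow(x$matrix), length(x$site_matrices)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Tidy a cell distance matrix into a long tibble
#'
#' @param x a `cell_dist` object.
#' @param ... unused.
#' @return a tibble with one row per unordered taxon pair.
#' @export
tidy.cell_dist <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(m)[idx[, 1]],
                 item2 = colnames(m)[idx[, 2]],
                 distance = m[idx])
}

#' Heatmap of a cell distance matrix
#'
#' @param object a `cell_dist` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cell_dist <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(item1 = rownames(m), item2 = colnames(m))
  df$distance <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$item2, .data$item1,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal()
}
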