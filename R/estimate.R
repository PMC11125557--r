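#' Joint log-likelihood of the reads at the selected sites
#'
#' For each site the mutation type is marginalized under its
#' Dirichlet-Categorical prior, the mutation statuses of all cells under
#' the Beta-Binomial count weight (a subset-sum dynamic program) and,
#' per cell, the dropout / amplification-error latent variables. Per-cell
#' branch sums are cached so repeated evaluations at new `(p_ado, p_ae)`
#' are cheap; the likelihood is invariant to site order.
#'
#' @param sites an `ld_sites` tibble.
#' @param p_ado,p_ae parameter values at which to evaluate.
#' @param alpha,a,b hyperparameters (see [model_params()]).
#' @param cache optional precomputed cache from [build_likelihood_cache()].
#' @return the log-likelihood.
#' @export
data_log_likelihood <- function(sites, p_ado, p_ae, alpha = 1, a = 1, b = 1,
                                cache = NULL) {
  if (is.null(cache)) cache <- build_likelihood_cache(sites, alpha)
  cpp_sites_loglik(cache, p_ado, p_ae, a, b)
}

#' Precompute the per-site likelihood caches
#'
#' @param sites an `ld_sites` tibble.
#' @param alpha mutation-type concentration parameter.
#' @return a list of per-site caches consumed by [data_log_likelihood()].
#' @export
build_likelihood_cache <- function(sites, alpha = 1) {
  lapply(sites$site, build_site_cache, alpha = alpha)
}

#' Metropolis-Hastings estimation of the dropout and amplification rates
#'
#' Random-walk Metropolis-Hastings on `(p_ado, p_ae)` with independent
#' Gaussian proposals (the proposal is symmetric, so the acceptance ratio
#' is the pure likelihood ratio under the uniform parameter priors;
#' proposals outside `[0, 1]` have prior density 0 and are rejected).
#' Several chains are run from independent initial values drawn from the
#' stated ranges; the point estimates are the pooled post-burn-in sample
#' means.
#'
#' @param sites an `ld_sites` tibble.
#' @param n_sites number of sites randomly subsampled (without
#'   replacement) for estimation.
#' @param n_iter iterations per chain.
#' @param n_chains number of chains.
#' @param proposal_sd standard deviation of the Gaussian proposals.
#' @param burn_in fraction of each chain discarded as burn-in.
#' @param p_ado_init,p_ae_init uniform ranges for the initial values.
#' @param alpha,a,b hyperparameters.
#' @param seed optional seed.
#' @return an object of class `mh_fit` with the pooled estimates, the full
#'   chains tibble and the configuration; see [tidy.mh_fit()] and
#'   [glance.mh_fit()].
#' @export
estimate_parameters <- function(sites, n_sites = 20, n_iter = 5000,
                                n_chains = 3, proposal_sd = 0.01,
                                burn_in = 0.2,
                                p_ado_init = c(0, 1), p_ae_init = c(0, 0.1),
                                alpha = 1, a = 1, b = 1, seed = NULL) {
  if (nrow(sites) == 0) stop("no sites available for parameter estimation")
  if (burn_in <= 0 || burn_in >= 1) stop("burn_in must be in (0, 1)")
  if (proposal_sd <= 0) stop("proposal_sd must be positive")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(sites), min(n_sites, nrow(sites)))
  sub <- sites[sort(idx), ]
  cache <- build_likelihood_cache(sub, alpha)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    cur <- c(runif(1, p_ado_init[1], p_ado_init[2]),
             runif(1, p_ae_init[1], p_ae_init[2]))
    cur_ll <- cpp_sites_loglik(cache, cur[1], cur[2], a, b)
    out <- matrix(NA_real_, n_iter, 3)
    acc <- logical(n_iter)
    for (it in seq_len(n_iter)) {
      prop <- cur + rnorm(2, 0, proposal_sd)
      if (all(prop >= 0) && all(prop <= 1)) {
        prop_ll <- cpp_sites_loglik(cache, prop[1], prop[2], a, b)
        if (log(runif(1)) < prop_ll - cur_ll) {
          cur <- prop
          cur_ll <- prop_ll
          acc[it] <- TRUE
        }
      }
      out[it, ] <- c(cur, cur_ll)
    }
    chains[[ch]] <- tibble::tibble(chain = ch, iter = seq_len(n_iter),
                                   p_ado = out[, 1], p_ae = out[, 2],
                                   log_lik = out[, 3], accepted = acc)
  }
  chains <- dplyr::bind_rows(chains)
  keep <- chains$iter > floor(burn_in * n_iter)
  est <- c(p_ado = mean(chains$p_ado[keep]), p_ae = mean(chains$p_ae[keep]))
  structure(list(estimates = est, chains = chains,
                 config = list(n_sites = nrow(sub), n_iter = n_iter,
                               n_chains = n_chains,
                               proposal_sd = proposal_sd, burn_in = burn_in,
                               a = a, b = b, alpha = alpha),
                 site_idx = sort(idx)),
            class = "mh_fit")
}

#' @export
print.mh_fit <- function(x, ...) {
  cat(sprintf(
    "Metropolis-Hastings fit (%d chains x %d iters, %d sites)\n",
    x$config$n_chains, x$config$n_iter, x$config$n_sites))
  cat(sprintf("  p_ado = %.4f, p_ae = %.3g (pooled post-burn-in means)\n",
              x$estimates["p_ado"], x$estimates["p_ae"]))
  invisible(x)
}

#' Tidy the parameter estimates of an MH fit
#'
#' @param x an `mh_fit`.
#' @param ... unused.
#' @return a tibble with one row per parameter: the pooled post-burn-in
#'   mean and the central 95% interval of the pooled samples.
#' @export
tidy.mh_fit <- function(x, ...) {
  keep <- x$chains$iter > floor(x$config$burn_in * x$config$n_iter)
  sub <- x$chains[keep, ]
  dplyr::bind_rows(lapply(c("p_ado", "p_ae"), function(p) {
    v <- sub[[p]]
    tibble::tibble(term = p, estimate = mean(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)))
  }))
}

#' One-row summary of an MH fit
#'
#' @param x an `mh_fit`.
#' @param ... unused.
#' @return a tibble with the estimates, the acceptance rate and the chain
#'   configuration.
#' @export
glance.mh_fit <- function(x, ...) {
  tibble::tibble(p_ado = unname(x$estimates["p_ado"]),
                 p_ae = unname(x$estimates["p_ae"]),
                 acceptance_rate = mean(x$chains$accepted),
                 n_sites = x$config$n_sites,
                 n_iter = x$config$n_iter,
                 n_chains = x$config$n_chains)
}

#' Trace plot of the MH chains
#'
#' @param object an `mh_fit`.
#' @param ... unused.
#' @return a ggplot object (one facet per parameter).
#' @export
autoplot.mh_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$chains, c("p_ado", "p_ae"),
                            names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(.data$iter, .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
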