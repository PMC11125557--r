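test_that("mutation types differ from bulk by one nucleotide", {
  z <- enumerate_mutation_types(c("A", "A"))
  expect_length(z, 3)
  expect_true(all(sapply(z, function(t) t[1] == "A" && t[2] != "A")))
  zp <- enumerate_mutation_types(c("AA", "AT"), cand_index = 1)
  expect_length(zp, 6)
  expect_true(any(sapply(zp, function(t) identical(t, c("AA", "GT")))))
  # every type differs from bulk at exactly one haplotype-position
  for (t in zp) {
    d <- sum(strsplit(t[1], "")[[1]] != c("A", "A")) +
      sum(strsplit(t[2], "")[[1]] != c("A", "T"))
    expect_equal(d, 1)
  }
})

test_that("mutation-type prior is Dirichlet-Categorical", {
  expect_equal(mutation_type_prior(rep(1, 3)), rep(1 / 3, 3))
  expect_equal(mutation_type_prior(rep(1, 6)), rep(1 / 6, 6))
  a <- c(2, 1, 1)
  p <- mutation_type_prior(a)
  # direct Beta-function evaluation
  expect_equal(p, beta(sum(a), 1) / beta(a, 1))
  expect_equal(sum(p), 1)
})

test_that("mutation-count weight integrates the Beta prior exactly", {
  expect_equal(mutation_count_weight(0, 2), 1 / 3)
  # binomial-weighted sum over m is 1 (uniform prior on the rate)
  for (C in c(2, 5, 10)) {
    tot <- sum(sapply(0:C, function(m) choose(C, m) * mutation_count_weight(m, C)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # C = 2, a = b = 1: four status vectors with probs (1/3, 1/6, 1/6, 1/3)
  w <- sapply(0:2, function(m) mutation_count_weight(m, 2))
  expect_equal(w, c(1 / 3, 1 / 6, 1 / 6, 1 / 3)[c(1, 2, 4)])
})

test_that("pair posterior equals 2^C enumeration", {
  params <- model_params(p_ado = 0.2, p_ae = 0.01)
  for (cfgi in list(list(Ls = c(2, 2), kind = "singleton"),
                    list(Ls = c(2, 3, 0, 2, 1), kind = "paired"),
                    list(Ls = c(1, 2, 2, 0, 1, 2, 3), kind = "singleton"))) {
    site <- make_site(cfgi$Ls, kind = cfgi$kind, seed = length(cfgi$Ls))
    post <- pair_posterior(site, 1, 2, params)
    bf <- oracle_pair_posterior(site, 1, 2, params)
    expect_equal(unclass(post), bf, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(post), 1, tolerance = 1e-10)
  }
})

test_that("C = 2 pair posterior degenerates to the 4-term sum", {
  params <- model_params(p_ado = 0.1, p_ae = 1e-3)
  site <- make_site(c(2, 2), kind = "singleton", seed = 2)
  post <- pair_posterior(site, 1, 2, params)
  bf <- oracle_pair_posterior(site, 1, 2, params)
  expect_equal(unclass(post), bf, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical read sets give an exchangeable posterior", {
  params <- model_params(p_ado = 0.1, p_ae = 1e-3)
  site <- make_site(c(3, 3, 2), kind = "singleton", seed = 5)
  site$cells[[2]] <- site$cells[[1]]
  post <- pair_posterior(site, 1, 2, params)
  expect_equal(post[1, 2], post[2, 1], tolerance = 1e-12)
})

test_that("site distances are probabilities with the stated fixed points", {
  p00 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(site_distance(p00), 0)
  pu <- matrix(0.25, 2, 2)
  expect_equal(site_distance(pu), 0.5)
  set.seed(8)
  site <- make_site(c(2, 2, 1), kind = "paired", seed = 8)
  post <- pair_posterior(site, 1, 2, model_params())
  d <- site_distance(post)
  expect_gte(d, 0)
  expect_lte(d, 1)
})

test_that("bulk distance is the marginal mutation posterior", {
  params <- model_params(p_ado = 0.15, p_ae = 0.01)
  site <- make_site(c(2, 2, 2), kind = "singleton", seed = 13)
  bd <- site_bulk_distance(site, 1, params)
  bf <- oracle_pair_posterior(site, 1, 2, params)
  expect_equal(bd, bf[2, 1] + bf[2, 2], tolerance = 1e-10)
})

test_that("distance aggregation averages co-covered sites only", {
  m1 <- matrix(0.2, 3, 3); diag(m1) <- 0
  m2 <- matrix(0.4, 3, 3); diag(m2) <- 0
  agg <- aggregate_distances(list(m1, m2))
  expect_equal(agg[1, 2], 0.3)
  # single-site aggregate equals the site matrix
  expect_equal(aggregate_distances(list(m1)), m1)
  # a cell without coverage at a site is excluded from its averages
  m2na <- m2
  m2na[1, ] <- m2na[, 1] <- NA
  diag(m2na) <- 0
  agg2 <- aggregate_distances(list(m1, m2na))
  expect_equal(agg2[1, 2], 0.2)
  expect_equal(agg2[2, 3], 0.3)
})

test_that("pairs with no co-covered sites are imputed with a warning", {
  m <- matrix(NA_real_, 3, 3)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.6
  expect_warning(agg <- aggregate_distances(list(m)), "imputing")
  expect_equal(agg[1, 3], mean(c(0.2, 0.6)))
  expect_equal(agg, t(agg))
})

test_that("aggregated matrices from real runs are well-formed", {
  cfg <- sim_config(n_cells = 5, genome_length = 3000, mu = 2, rho = 1,
                    p_ado = 0.1, p_ae = 1e-3, lambda = 8, seed = 14)
  ds <- simulate_dataset(cfg)
  sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells)
  skip_if(nrow(sites) == 0, "no sites in this tiny simulation")
  d <- compute_distances(sites, model_params(0.1, 1e-3))
  expect_equal(d$matrix, t(d$matrix))
  expect_true(all(diag(d$matrix) == 0))
  expect_true(all(d$matrix >= 0 & d$matrix <= 1))
  td <- tidy(d)
  expect_equal(nrow(td), choose(6, 2))
})

test_that("shared mutations shorten pairwise distances at their site", {
  cfg <- sim_config(n_cells = 6, genome_length = 4000, mu = 3, rho = 1,
                    p_ado = 0, p_ae = 0, lambda = 20, seed = 31)
  ds <- simulate_dataset(cfg)
  sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells)
  d <- compute_distances(sites, model_params(1e-3, 1e-5))
  m <- ds$mutations
  checked <- 0
  for (i in seq_len(nrow(sites))) {
    j <- which(m$locus == sites$pos[i])
    if (length(j) != 1) next
    carriers <- which(ds$mut_cells[j, ])
    non <- setdiff(seq_len(cfg$n_cells), carriers)
    if (length(carriers) < 2 || length(non) < 1) next
    M <- d$site_matrices[[i]]
    concordant <- M[carriers[1], carriers[2]]
    discordant <- M[carriers[1], non[1]]
    if (is.na(concordant) || is.na(discordant)) next
    expect_lt(concordant, discordant)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})
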