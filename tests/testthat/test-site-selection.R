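# build a read tibble from per-read (cell, start, bases) with uniform qual
mk_reads <- function(cell, start, bases, phred = 40) {
  tibble::tibble(cell = cell, start = start, bases = bases,
                 quals = strrep(intToUtf8(phred + 33), nchar(bases)))
}

test_that("bulk reference calls enforce depth and majority thresholds", {
  bulk <- mk_reads(NA, rep(0L, 12), rep("A", 12))
  expect_equal(call_bulk_reference(bulk, 0), "A")
  expect_true(is.na(call_bulk_reference(mk_reads(NA, rep(0L, 9), rep("A", 9)), 0)))
  mixed <- mk_reads(NA, rep(0L, 10), c(rep("A", 7), rep("C", 3)))
  expect_true(is.na(call_bulk_reference(mixed, 0))) # 0.7 < 0.8
  ok8 <- mk_reads(NA, rep(0L, 10), c(rep("A", 8), rep("C", 2)))
  expect_equal(call_bulk_reference(ok8, 0), "A") # non-strict >= 0.8
})

test_that("gSNV calls require depth 10 and alternative frequency 0.2", {
  het <- mk_reads(NA, rep(0L, 20), c(rep("A", 10), rep("T", 10)))
  g <- call_gsnvs(het)
  expect_equal(nrow(g), 1)
  expect_setequal(c(g$a1, g$a2), c("A", "T"))
  low <- mk_reads(NA, rep(0L, 20), c(rep("A", 19), "T"))
  expect_equal(nrow(call_gsnvs(low)), 0)
  shallow <- mk_reads(NA, rep(0L, 8), c(rep("A", 4), rep("T", 4)))
  expect_equal(nrow(call_gsnvs(shallow)), 0)
})

test_that("gSNV validation needs two displaying cells at 20%", {
  two <- mk_reads(rep(1:2, each = 10), rep(0L, 20),
                  rep(c(rep("A", 5), rep("T", 5)), 2))
  expect_true(validate_gsnv_in_cells(two, 0, c("A", "T")))
  one <- mk_reads(c(rep(1L, 10), rep(2L, 10)), rep(0L, 20),
                  c(rep(c("A", "T"), 5), rep("A", 10)))
  expect_false(validate_gsnv_in_cells(one, 0, c("A", "T")))
  weak <- mk_reads(rep(1:3, each = 10), rep(0L, 30),
                   rep(c(rep("A", 9), "T"), 3)) # 10% < 20%
  expect_false(validate_gsnv_in_cells(weak, 0, c("A", "T")))
})

test_that("candidate selection keeps 2..C-1 agreeing cells only", {
  bulk <- mk_reads(NA, rep(0L, 12), rep("A", 12))
  C <- 10
  # 3 cells half G, the rest all A
  cells <- do.call(rbind, lapply(1:C, function(c) {
    b <- if (c <= 3) c(rep("G", 5), rep("A", 5)) else rep("A", 10)
    mk_reads(rep(c, 10), rep(0L, 10), b)
  }))
  got <- select_candidates(cells, bulk, C)
  expect_equal(got$pos, 0L)
  expect_equal(got$alt, "G")
  expect_equal(got$n_alt_cells, 3L)
  # a single alternative cell does not qualify
  cells1 <- do.call(rbind, lapply(1:C, function(c) {
    b <- if (c == 1) rep("G", 10) else rep("A", 10)
    mk_reads(rep(c, 10), rep(0L, 10), b)
  }))
  expect_equal(nrow(select_candidates(cells1, bulk, C)), 0)
  # all cells alternative does not qualify either
  cellsC <- do.call(rbind, lapply(1:C, function(c) {
    mk_reads(rep(c, 10), rep(0L, 10), rep("G", 10))
  }))
  expect_equal(nrow(select_candidates(cellsC, bulk, C)), 0)
})

test_that("candidates pair with the closest co-covered gSNV", {
  # reads of length 4 starting at 0: cover positions 0..3
  # candidate at 0; gSNVs at 1 (near) and 3 (far)
  gsnvs <- tibble::tibble(pos = c(1L, 3L), a1 = c("A", "C"), a2 = c("T", "G"))
  reads <- mk_reads(rep(1:2, each = 10), rep(0L, 20),
                    rep(c("GACC", "GTCG"), 10))
  p <- pair_with_gsnv(0L, gsnvs, reads)
  expect_equal(p$gsnv_pos, 1L)
  # when the near gSNV fails the co-covering re-check, the far one is used
  reads2 <- mk_reads(rep(1:2, each = 10), rep(0L, 20),
                     rep(c("GACC", "GACG"), 10)) # position 1 always A
  p2 <- pair_with_gsnv(0L, gsnvs, reads2)
  expect_equal(p2$gsnv_pos, 3L)
  # no qualifying gSNV at all
  reads3 <- mk_reads(rep(1:2, each = 10), rep(0L, 20), rep("GACC", 20))
  expect_null(pair_with_gsnv(0L, gsnvs, reads3))
})

test_that("fully phased noiseless simulations yield only paired sites", {
  cfg <- sim_config(n_cells = 6, genome_length = 4000, mu = 3, rho = 1,
                    p_ado = 0, p_ae = 0, lambda = 20, seed = 21)
  ds <- simulate_dataset(cfg)
  sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells, mode = "hybrid")
  expect_gt(nrow(sites), 0)
  expect_true(all(sites$kind == "paired"))
  expect_true(all(sites$gsnv_pos == sites$pos - 1L))
  # singleton mode on the same data keeps the same candidate positions
  s2 <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells, mode = "singleton")
  expect_equal(s2$pos, sites$pos)
  expect_true(all(s2$kind == "singleton"))
})

test_that("selected sites recover the threshold-eligible mutation loci", {
  cfg <- sim_config(n_cells = 6, genome_length = 4000, mu = 3, rho = 1,
                    p_ado = 0, p_ae = 0, lambda = 20, seed = 22)
  ds <- simulate_dataset(cfg)
  sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells)
  # no false positives: every selected site is a true mutation locus
  expect_true(all(sites$pos %in% ds$mutations$locus))
  # the eligible set recomputed from the reads: loci where 2..C-1 cells show
  # the alternative in >= 20% of >= 2 reads
  long <- lineagedist:::reads_long(ds$reads)
  eligible <- vapply(seq_len(nrow(ds$mutations)), function(i) {
    loc <- ds$mutations$locus[i]
    alt <- lineagedist:::NUC[ds$mutations$alt[i] + 1]
    at <- long[long$pos == loc, ]
    n_alt <- sum(vapply(unique(at$cell), function(c) {
      b <- at$base[at$cell == c]
      length(b) >= 2 && mean(b == alt) >= 0.2
    }, logical(1)))
    n_alt >= 2 && n_alt <= cfg$n_cells - 1
  }, logical(1))
  expect_setequal(sites$pos, ds$mutations$locus[eligible])
})

test_that("every emitted site re-satisfies the selection thresholds", {
  cfg <- sim_config(n_cells = 5, genome_length = 3000, mu = 3, rho = 1,
                    p_ado = 0.1, p_ae = 1e-3, lambda = 10, seed = 23)
  ds <- simulate_dataset(cfg)
  sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells)
  long <- lineagedist:::reads_long(ds$bulk_reads)
  for (i in seq_len(nrow(sites))) {
    s <- sites$site[[i]]
    # bulk support: depth >= 10 and >= 80% reference at the candidate
    ref <- substr(s$bulk[1], 1, 1)
    at <- long[long$pos == s$positions[1], ]
    expect_gte(nrow(at), 10)
    expect_gte(mean(at$base == ref), 0.8)
    # per-cell listed coverage matches the matrices
    for (obs in s$cells) {
      if (is.null(obs)) next
      expect_equal(nrow(obs$bases), nrow(obs$error_probs))
      expect_true(all(obs$error_probs > 0 & obs$error_probs <= 1, na.rm = TRUE))
    }
  }
})

test_that("selection is invariant to read input order", {
  cfg <- sim_config(n_cells = 5, genome_length = 2000, mu = 2, rho = 1,
                    p_ado = 0.1, lambda = 10, seed = 24)
  ds <- simulate_dataset(cfg)
  s1 <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells)
  set.seed(99)
  shuf <- ds$reads[sample(nrow(ds$reads)), ]
  s2 <- select_sites(shuf, ds$bulk_reads, cfg$n_cells)
  expect_equal(s1$pos, s2$pos)
  expect_equal(s1$kind, s2$kind)
  d1 <- compute_distances(s1, model_params())
  d2 <- compute_distances(s2, model_params())
  expect_equal(d1$matrix, d2$matrix, tolerance = 1e-12)
})

test_that("empty input yields an empty site set, not an error", {
  empty <- tibble::tibble(cell = integer(0), start = integer(0),
                          bases = character(0), quals = character(0))
  s <- select_sites(empty, empty, 4)
  expect_equal(nrow(s), 0)
})
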