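test_that("lineage trees are rooted binary with 2(C-1) edges", {
  tr <- generate_lineage_tree(10, seed = 1)
  expect_equal(length(tr$tip.label), 10)
  expect_equal(nrow(tr$edge), 18)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  t1 <- generate_lineage_tree(3, seed = 5)
  t2 <- generate_lineage_tree(3, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(generate_lineage_tree(2), "n_cells")
})

test_that("mutation assignment hits the printed count with one per edge", {
  tr <- generate_lineage_tree(10, seed = 2)
  mm <- assign_mutations(tr, 10, 1e5, seed = 3)
  expect_equal(nrow(mm), 180)
  mm2 <- assign_mutations(tr, 20, 1e5, seed = 3)
  expect_equal(nrow(mm2), 360)
  expect_true(all(mm$locus %% 2 == 1))
  expect_equal(anyDuplicated(mm$locus), 0)
  expect_true(all(tabulate(mm$edge, nrow(tr$edge)) >= 1))
  expect_error(assign_mutations(tr, 10, 300, seed = 1), "genome too short")
})

test_that("genomes carry the configured gSNVs and inherited mutations", {
  cfg <- sim_config(n_cells = 4, genome_length = 10000, mu = 2, rho = 0.01,
                    seed = 4)
  tr <- generate_lineage_tree(4, seed = 4)
  mm <- assign_mutations(tr, 2, 10000, seed = 4)
  gen <- generate_genomes(cfg, tr, mm, seed = 4)
  expect_equal(length(gen$gsnv_loci), round(0.01 * 5000))
  expect_true(all(gen$gsnv_loci %% 2 == 0))
  het <- gen$h1[gen$gsnv_loci + 1] != gen$h2[gen$gsnv_loci + 1]
  expect_true(all(het))
  hom <- setdiff(seq(0, 9998, by = 2), gen$gsnv_loci)
  expect_true(all(gen$h1[hom + 1] == gen$h2[hom + 1]))
  # rho = 1: every even position is a gSNV
  cfg1 <- sim_config(n_cells = 4, genome_length = 1000, mu = 2, rho = 1,
                     seed = 4)
  gen1 <- generate_genomes(cfg1, tr, assign_mutations(tr, 2, 1000, seed = 4),
                           seed = 4)
  expect_equal(gen1$gsnv_loci, seq(0L, 998L, by = 2L))
})

test_that("cell genomes differ from bulk exactly at inherited loci", {
  cfg <- sim_config(n_cells = 5, genome_length = 4000, mu = 2, rho = 0.5,
                    seed = 9)
  ds <- simulate_dataset(cfg)
  for (cell in c(1, 3, 5)) {
    g <- cell_genome(ds, cell)
    diffs <- sort(union(which(g$h1 != ds$h1), which(g$h2 != ds$h2))) - 1L
    mine <- sort(ds$mutations$locus[ds$mut_cells[, cell]])
    expect_equal(diffs, mine)
  }
})

test_that("dropout masks are Bernoulli with the stated rate", {
  m0 <- apply_ado_mask(3, 100, 0, seed = 1)
  expect_false(any(m0$d1) || any(m0$d2))
  m1 <- apply_ado_mask(3, 100, 1, seed = 1)
  expect_true(all(m1$d1) && all(m1$d2))
  m <- apply_ado_mask(10, 5000, 0.2, seed = 2)
  frac <- mean(c(m$d1, m$d2))
  n <- 2 * 10 * 5000
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("the urn amplifier respects dropout and error-free limits", {
  out <- amplify_site(character(0), 10, 0.5, seed = 1)
  expect_length(out, 0)
  one <- amplify_site("AG", 7, 0, seed = 2)
  expect_true(all(one == "AG"))
  expect_length(one, 7)
  # two initial balls, two final balls: the only reachable split is (1, 1)
  splits <- replicate(200, {
    f <- amplify_site(c("A", "G"), 2, 0)
    c(sum(f == "A"), sum(f == "G"))
  })
  expect_true(all(splits == 1))
})

test_that("sequencing respects the Phred range and error rate", {
  set.seed(6)
  frags <- rep("AA", 300)
  reads <- sequence_reads(frags, phred_range = c(30, 42))
  expect_equal(nrow(reads), 300)
  phred <- utf8ToInt(paste(reads$quals, collapse = "")) - 33
  expect_true(all(phred >= 30 & phred <= 42))
  # at fixed rho = 30 the per-base miscall rate is 1e-3
  set.seed(7)
  n <- 5e5
  reads <- sequence_reads(rep("A", n), phred_range = c(30, 30))
  err <- mean(reads$bases != "A")
  expect_lt(abs(err - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / n))
  expect_equal(nrow(sequence_reads(character(0))), 0)
})

test_that("bulk reads replicate both haplotypes without error", {
  h1 <- c(0L, 1L, 2L, 3L)
  h2 <- c(0L, 3L, 2L, 3L) # gSNV at position 1
  br <- make_bulk_reads(h1, h2, bulk_copies = 15, read_length = 2)
  expect_equal(nrow(br), 2 * 15 * 2)
  at0 <- br[br$start == 0, ]
  expect_equal(nrow(at0), 30)
  second <- substr(at0$bases, 2, 2)
  expect_equal(sum(second == "C"), 15)
  expect_equal(sum(second == "T"), 15)
  first <- substr(at0$bases, 1, 1)
  expect_true(all(first == "A"))
})

test_that("full simulation is seed-deterministic", {
  cfg <- sim_config(n_cells = 4, genome_length = 2000, mu = 2, rho = 1,
                    lambda = 5, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$reads, d2$reads)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$mutations, d2$mutations)
})

test_that("noiseless pileups reflect the ground-truth genotypes", {
  cfg <- sim_config(n_cells = 4, genome_length = 2000, mu = 2, rho = 1,
                    p_ado = 0, p_ae = 0, lambda = 20, seed = 15,
                    phred_range = c(60, 60)) # effectively error-free reads
  ds <- simulate_dataset(cfg)
  long <- lineagedist:::reads_long(ds$reads)
  for (i in seq_len(min(6, nrow(ds$mutations)))) {
    loc <- ds$mutations$locus[i]
    alt <- lineagedist:::NUC[ds$mutations$alt[i] + 1]
    at <- long[long$pos == loc, ]
    for (cell in seq_len(cfg$n_cells)) {
      b <- at$base[at$cell == cell]
      if (length(b) == 0) next
      if (ds$mut_cells[i, cell]) {
        expect_true(alt %in% b)
      } else {
        expect_false(alt %in% b)
      }
    }
  }
})
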