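test_that("similarity is 1 on identical trees and 0 on disjoint ones", {
  set.seed(40)
  tr <- ape::rtree(10)
  expect_equal(rf_similarity(tr, tr), 1)
  cat6 <- ape::read.tree(text = "(1,(2,(3,(4,(5,6)))));")
  other <- ape::read.tree(text = "((1,6),((2,5),(3,4)));")
  expect_equal(rf_similarity(cat6, other), 0)
})

test_that("similarity equals the bipartition-set computation", {
  cat6 <- ape::read.tree(text = "(1,(2,(3,(4,(5,6)))));")
  bal6 <- ape::read.tree(text = "((1,2),((3,4),(5,6)));")
  # by hand: caterpillar splits {56},{456},{3456}; balanced {12},{34},{56}
  # (the {12} and {3456} splits are complements, hence identical); shared:
  # {56} and {12|3456}; RF = 1 + 1 = 2; I_B = 6
  expect_equal(rf_similarity(cat6, bal6), 1 - 2 / 6)
  # symmetry
  expect_equal(rf_similarity(bal6, cat6), rf_similarity(cat6, bal6))
})

test_that("similarity agrees with an independent RF implementation", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (i in 1:10) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    t2$tip.label <- sample(t1$tip.label)
    rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
    ib <- 2 * (8 - 3) # both trees binary: 5 internal edges each
    expect_equal(rf_similarity(t1, t2), 1 - rf / ib)
  }
})

test_that("differing leaf sets are rejected", {
  t1 <- ape::rtree(5)
  t2 <- ape::rtree(5)
  t2$tip.label <- paste0("x", 1:5)
  expect_error(rf_similarity(t1, t2), "leaf sets")
})

test_that("TBE is 1 when every bootstrap tree matches the reference", {
  set.seed(42)
  ref <- ape::rtree(10)
  boots <- rep(list(ref), 100)
  sup <- tbe_supports(ref, boots)
  expect_equal(nrow(sup), 7) # binary 10-leaf tree: 10 - 3 internal edges
  expect_true(all(sup$support == 1))
})

test_that("cherry supports reduce to the bootstrap proportion", {
  # reference with cherry (a,b); bootstrap sets where the cherry appears in
  # a known fraction of trees
  ref <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  with_cherry <- ape::read.tree(text = "((a,b),(d,(c,e)));")
  without <- ape::read.tree(text = "((a,c),(b,(d,e)));")
  boots <- c(rep(list(with_cherry), 3), rep(list(without), 1))
  sup <- tbe_supports(ref, boots)
  cherry <- sup[sup$clade == "a,b", ]
  expect_equal(cherry$p, 2)
  expect_equal(cherry$support, 3 / 4)
})

test_that("a maximally distant absent edge gives support one half", {
  # 6-leaf reference; an internal edge with p = 3 and a bootstrap tree where
  # its transfer distance is p - 1 = 2 gives per-tree support 0; mixing it
  # 1:1 with exact copies gives 0.5
  ref <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  sup0 <- tbe_supports(ref, list(ref))
  target <- which(sup0$p == 3)
  far <- ape::read.tree(text = "(((a,d),b),((c,e),f));")
  sup_far <- tbe_supports(ref, list(far))
  expect_equal(sup_far$support[target], 0)
  mixed <- tbe_supports(ref, list(ref, far))
  expect_equal(mixed$support[target], 0.5)
})

test_that("the Hamming formulation equals brute-force leaf removal", {
  set.seed(43)
  for (rep in 1:5) {
    ref <- ape::rtree(7)
    boot <- ape::rtree(7)
    boot$tip.label <- sample(ref$tip.label)
    rb <- lineagedist:::cell_bipartitions(ref)
    bs <- lineagedist:::all_splits_with_trivial(boot)
    n <- length(rb$labels)
    for (i in seq_len(nrow(rb$splits))) {
      ham <- lineagedist:::min_transfer_distance(rb$splits[i, ], bs$splits, n)
      bf <- oracle_transfer_distance(rb$splits[i, ], boot, rb$labels)
      expect_equal(ham, bf, info = sprintf("rep %d split %d", rep, i))
    }
  }
})

test_that("TBE never falls below the Felsenstein proportion", {
  set.seed(44)
  for (rep in 1:20) {
    ref <- ape::rtree(8)
    boots <- lapply(1:10, function(i) {
      b <- ape::rtree(8)
      b$tip.label <- sample(ref$tip.label)
      b
    })
    sup <- tbe_supports(ref, boots)
    rb <- lineagedist:::cell_bipartitions(ref)
    keys <- lineagedist:::split_keys(rb$splits)
    fels <- vapply(seq_len(nrow(rb$splits)), function(i) {
      mean(vapply(boots, function(b) {
        bk <- lineagedist:::split_keys(lineagedist:::cell_bipartitions(b)$splits)
        keys[i] %in% bk
      }, logical(1)))
    }, numeric(1))
    expect_true(all(sup$support >= fels - 1e-12))
  }
})

test_that("supports project onto the reference topology and round-trip", {
  set.seed(45)
  ref <- ape::rtree(8)
  boots <- lapply(1:5, function(i) {
    b <- ape::rtree(8)
    b$tip.label <- sample(ref$tip.label)
    b
  })
  sup <- tbe_supports(ref, boots)
  ann <- project_supports(ref, sup)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(ann, tmp)
  back <- ape::read.tree(tmp)
  vals <- suppressWarnings(as.numeric(back$node.label))
  vals <- vals[!is.na(vals)]
  # both children of the root carry the same (complementary) split, so we
  # compare the value sets
  expect_setequal(unique(vals), unique(round(sup$support, 2)))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(rf_similarity(back, ref), 1)
})
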