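# Exact branch-and-bound, heuristic search and the TBR neighbourhood.

test_that("topology enumeration yields the double-factorial counts, uniquely", {
  expect_length(enumerate_topologies(4), 3)
  expect_length(enumerate_topologies(6), 105)
  t8 <- enumerate_topologies(8)
  expect_length(t8, 10395)
  keys <- vapply(t8, topo_key, character(1))
  expect_equal(length(unique(keys)), 10395)
  expect_error(enumerate_topologies(11), "guarded")
})

test_that("branch and bound equals exhaustive enumeration on random instances", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(6:8, 1)
    tr <- simulate_tree(n)
    m <- simulate_matrix(tr, 12, change_prob = 0.15,
                         fraction_missing = 0.05, fraction_ambiguous = 0.02)
    topo <- enumerate_topologies(taxa_labels(m))
    lens <- vapply(topo, function(t) tree_length(t, m)$total_length,
                   integer(1))
    res <- branch_and_bound(m)
    expect_equal(res$best_length, min(lens))
    expect_equal(res$n_trees, sum(lens == min(lens)))
    oracle_keys <- sort(vapply(topo[lens == min(lens)], topo_key,
                               character(1)))
    bab_keys <- sort(vapply(res$trees, topo_key, character(1)))
    expect_equal(bab_keys, oracle_keys)
  }
})

test_that("every reported optimal tree attains the reported length", {
  set.seed(62)
  tr <- simulate_tree(7)
  m <- simulate_matrix(tr, 10, change_prob = 0.2)
  res <- branch_and_bound(m)
  lens <- vapply(res$trees, function(t) tree_length(t, m)$total_length,
                 integer(1))
  expect_true(all(lens == res$best_length))
  expect_equal(res$n_trees, length(unique(vapply(res$trees, topo_key,
                                                 character(1)))))
})

test_that("heuristic search finds the exact optimum and is deterministic", {
  set.seed(63)
  # 5 taxa: compare against all 15 topologies
  tr5 <- simulate_tree(5)
  m5 <- simulate_matrix(tr5, 8, change_prob = 0.2)
  lens <- vapply(enumerate_topologies(taxa_labels(m5)),
                 function(t) tree_length(t, m5)$total_length, integer(1))
  h5 <- heuristic_search(m5, n_addition_replicates = 3, seed = 9)
  expect_equal(h5$best_length, min(lens))

  m <- coronal_matrix()
  h1 <- heuristic_search(m, n_addition_replicates = 3, seed = 7,
                         max_trees = 50)
  h2 <- heuristic_search(m, n_addition_replicates = 3, seed = 7,
                         max_trees = 50)
  expect_equal(h1$best_length, h2$best_length)
  expect_equal(write_newick(h1$trees), write_newick(h2$trees))
  # a heuristic search can never beat the exact optimum, and here ties it
  bb <- branch_and_bound(m)
  expect_equal(h1$best_length, bb$best_length)
})

test_that("TBR neighbourhood has the expected structure", {
  # n = 4: the neighbourhood is exactly the two alternative topologies
  tr4 <- read_newick(text = "((A,B),(C,D));")
  nb4 <- tbr_neighbors(tr4)
  expect_length(nb4, 2)
  keys <- vapply(nb4, topo_key, character(1))
  expect_false(topo_key(tr4) %in% keys)

  set.seed(71)
  tr6 <- simulate_tree(6)
  nb6 <- tbr_neighbors(tr6)
  for (t in nb6) {
    expect_setequal(t$tip.label, tr6$tip.label)
    expect_equal(nrow(ape::unroot(t)$edge), 2 * 6 - 3)
  }
  # superset of the NNI neighbourhood, identified independently as the
  # topologies differing from tr6 by exactly one bipartition
  all6 <- enumerate_topologies(tr6$tip.label)
  self <- mpclad:::.tree_splits(tr6)
  self_keys <- vapply(self, mpclad:::.split_key, character(1))
  nni_keys <- character()
  for (t in all6) {
    k <- vapply(mpclad:::.tree_splits(t), mpclad:::.split_key, character(1))
    if (length(setdiff(self_keys, k)) == 1) {
      nni_keys <- c(nni_keys, topo_key(t))
    }
  }
  expect_gt(length(nni_keys), 0)
  expect_true(all(nni_keys %in% vapply(nb6, topo_key, character(1))))
})
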