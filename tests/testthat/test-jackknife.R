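# Jackknife support: determinism, degenerate limits, recovery of true
# clades on clean data, and annotation onto consensus trees.

test_that("jackknife is deterministic under a fixed seed", {
  set.seed(101)
  tr <- simulate_tree(8)
  m <- split_marker_matrix(tr, k = 3)
  j1 <- jackknife(m, replicates = 20, deletion = 0.3, seed = 11,
                  n_addition_replicates = 3)
  j2 <- jackknife(m, replicates = 20, deletion = 0.3, seed = 11,
                  n_addition_replicates = 3)
  expect_identical(j1$support, j2$support)
  j3 <- jackknife(m, replicates = 20, deletion = 0.3, seed = 12,
                  n_addition_replicates = 3)
  expect_false(identical(j1$support$support, j3$support$support))
})

test_that("support does not depend on the matrix row order", {
  set.seed(102)
  tr <- simulate_tree(7)
  m <- split_marker_matrix(tr, k = 2)
  perm <- sample(n_taxa(m))
  mp <- char_matrix(
    matrix(mpclad:::.cell_symbol(m$cells[perm, ], m$tags[perm, ]),
           nrow = n_taxa(m),
           dimnames = list(taxa_labels(m)[perm], NULL)))
  j1 <- jackknife(m, replicates = 15, seed = 4, n_addition_replicates = 3)
  j2 <- jackknife(mp, replicates = 15, seed = 4, n_addition_replicates = 3)
  expect_equal(j1$support[order(j1$support$bipartition), ],
               j2$support[order(j2$support$bipartition), ])
})

test_that("the vanishing-deletion limit reproduces the full-data consensus", {
  set.seed(103)
  tr <- simulate_tree(7)
  m <- split_marker_matrix(tr, k = 2)
  # deletion probability so small that no character is ever removed
  jk <- jackknife(m, replicates = 15, deletion = 1e-12, seed = 2,
                  n_addition_replicates = 3)
  full <- heuristic_search(m, n_addition_replicates = 3, seed = 2)
  strict <- strict_consensus(full$trees)
  sk <- vapply(strict$splits$clade, mpclad:::.split_key, character(1))
  jk_keys <- vapply(jk$support$clade, mpclad:::.split_key, character(1))
  expect_true(all(sk %in% jk_keys))
  expect_true(all(jk$support$support[match(sk, jk_keys)] == 100))
})

test_that("true clades of homoplasy-free data earn high support", {
  set.seed(104)
  tr <- simulate_tree(8)
  m <- split_marker_matrix(tr, k = 10) # 10 clean characters per clade
  jk <- jackknife(m, replicates = 200, deletion = 0.3, seed = 6,
                  n_addition_replicates = 3)
  truth <- vapply(mpclad:::.tree_splits(tr), mpclad:::.split_key,
                  character(1))
  got <- vapply(jk$support$clade, mpclad:::.split_key, character(1))
  sup <- jk$support$support[match(truth, got)]
  expect_false(anyNA(sup))
  expect_true(all(sup > 95))
})

test_that("fixed-count deletion and fractional weighting are available", {
  set.seed(105)
  tr <- simulate_tree(6)
  m <- split_marker_matrix(tr, k = 3)
  jf <- jackknife(m, replicates = 10, seed = 3, fixed_count = 2,
                  n_addition_replicates = 2)
  expect_true(all(jf$replicates$n_deleted == 2))
  jw <- jackknife(m, replicates = 10, seed = 3, weighting = "fractional",
                  n_addition_replicates = 2)
  expect_true(all(jw$support$support >= 0 & jw$support$support <= 100))
})

test_that("annotation attaches support to consensus splits idempotently", {
  set.seed(106)
  tr <- simulate_tree(7)
  m <- split_marker_matrix(tr, k = 4)
  res <- heuristic_search(m, n_addition_replicates = 3, seed = 8)
  cons <- majority_rule(res$trees)
  jk <- jackknife(m, replicates = 20, seed = 9, n_addition_replicates = 3)
  ann <- annotate_support(cons, jk)
  expect_true("jackknife" %in% names(ann$splits))
  ok <- !is.na(ann$splits$jackknife)
  expect_true(all(ann$splits$jackknife[ok] >= 0 &
                    ann$splits$jackknife[ok] <= 100))
  expect_true(all(ann$splits$frequency >= 0 & ann$splits$frequency <= 100))
  ann2 <- annotate_support(ann, jk)
  expect_identical(ann$splits, ann2$splits)
  expect_identical(write_newick(ann$tree), write_newick(ann2$tree))
})
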