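# Bipartition bookkeeping, strict and majority-rule consensus, rooting.

test_that("bipartitions: counts, identity under re-rooting", {
  tr <- read_newick(text = "(A,B,(C,D));")
  bp <- bipartitions(tr)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$clade[[1]], c("C", "D"))

  set.seed(81)
  t20 <- simulate_tree(20)
  expect_equal(nrow(bipartitions(t20)), 17) # n - 3

  # split sets identify unrooted topologies regardless of rooting
  for (rep in 1:5) {
    t8 <- simulate_tree(8)
    og <- sample(t8$tip.label, 1)
    rerooted <- ape::root(t8, outgroup = og, resolve.root = TRUE)
    expect_equal(topo_key(t8), topo_key(rerooted))
  }
})

test_that("consensus of identical trees is that tree at 100%", {
  set.seed(82)
  t7 <- simulate_tree(7)
  trees <- c(t7, t7, t7)
  class(trees) <- "multiPhylo"
  for (cons in list(strict_consensus(trees), majority_rule(trees))) {
    expect_equal(nrow(cons$splits), 4) # n - 3
    expect_true(all(cons$splits$frequency == 100))
    expect_equal(topo_key(cons$tree), topo_key(t7))
  }
})

test_that("majority rule matches a hand-counted 5-leaf example", {
  t1 <- read_newick(text = "((A,B),(C,D),E);")
  t2 <- read_newick(text = "((A,C),(B,D),E);")
  trees <- c(t1, t2, t1)
  class(trees) <- "multiPhylo"
  cons <- majority_rule(trees)
  got <- cons$splits[order(cons$splits$bipartition), ]
  # hand count: {A,B} (stored by its side away from the reference taxon A,
  # i.e. {C,D,E}) and {C,D} each occur in 2 of 3 trees; {B,D} only once
  expect_equal(got$bipartition, c("C, D", "C, D, E"))
  expect_equal(got$frequency, rep(100 * 2 / 3, 2), tolerance = 1e-9)
  expect_false(any(grepl("^B, D$", cons$splits$bipartition)))
  # strict consensus of a conflicted set keeps nothing
  expect_equal(nrow(strict_consensus(trees)$splits), 0)
})

test_that("consensus agrees with the independent ape implementation", {
  set.seed(83)
  base <- simulate_tree(9)
  trees <- c(list(base), lapply(1:6, function(i) {
    nb <- tbr_neighbors(base)
    nb[[sample(length(nb), 1)]]
  }))
  class(trees) <- "multiPhylo"
  mine <- majority_rule(trees)
  ref <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  expect_equal(topo_key(mine$tree), topo_key(ref))
  mine_s <- strict_consensus(trees)
  ref_s <- ape::consensus(trees, p = 1, check.labels = TRUE)
  expect_equal(topo_key(mine_s$tree), topo_key(ref_s))
})

test_that("majority-rule bipartitions are mutually compatible", {
  set.seed(84)
  for (rep in 1:3) {
    # overlapping tree sets: a base tree plus TBR perturbations, so many
    # splits are shared and the majority set is non-trivial
    base <- simulate_tree(8)
    nb <- tbr_neighbors(base)
    trees <- c(list(base, base, base, base), sample(nb, 3))
    class(trees) <- "multiPhylo"
    cons <- majority_rule(trees)
    cl <- cons$splits$clade
    tips <- sort(base$tip.label)
    expect_gte(length(cl), 2)
    expect_true(all(cons$splits$frequency > 50))
    for (i in seq_along(cl)) {
      for (j in seq_len(i - 1)) {
        a <- cl[[i]]
        b <- cl[[j]]
        compatible <- length(intersect(a, b)) == 0 ||
          all(a %in% b) || all(b %in% a) ||
          length(union(a, b)) == length(tips) - 1
        expect_true(compatible)
      }
    }
  }
})

test_that("consensus demands a common leaf set", {
  set.seed(85)
  t1 <- simulate_tree(6)
  t2 <- simulate_tree(7)
  expect_error(strict_consensus(list(t1, t2)), "tree 2")
})

test_that("rooting for display splits outgroups from ingroup", {
  tr <- read_newick(text = "((A,B),(C,(D,E)));")
  rooted <- root_for_display(ape::unroot(tr), c("A", "B"))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1, 2]
  clades <- mpclad:::.node_clades(rooted)
  sides <- lapply(kids, function(k) clades[[k]])
  expect_true(any(vapply(sides, function(s) setequal(s, c("A", "B")),
                         logical(1))))
  # single outgroup roots on its pendant edge
  r1 <- root_for_display(ape::unroot(tr), "D")
  expect_true("D" %in% r1$tip.label)
  expect_equal(topo_key(r1), topo_key(tr))
  # non-monophyletic outgroup falls back with a warning
  expect_warning(root_for_display(ape::unroot(tr), c("A", "D")),
                 "not a clade")
})
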