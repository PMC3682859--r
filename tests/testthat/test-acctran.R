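# ACCTRAN reconstruction, apomorphy mapping and the all-trees intersection.

test_that("acctran reconstructs forced cases exactly", {
  tr <- ape::root(ape::unroot(quartet_tree()), outgroup = "A",
                  resolve.root = TRUE)
  # constant column: everything one state, zero changes
  res <- acctran_states(tr, c(A = "1", B = "1", C = "1", D = "1"))
  expect_equal(res$steps, 0)
  expect_true(all(res$states == 1))
  expect_equal(nrow(res$changes), 0)

  # 0011 on ((A,B),(C,D)) rooted at A: the single change subtends (C,D)
  res2 <- acctran_states(tr, c(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(res2$steps, 1)
  expect_equal(nrow(res2$changes), 1)
  clades <- mpclad:::.node_clades(tr)
  expect_equal(clades[[res2$changes$node[1]]], c("C", "D"))
  expect_equal(res2$changes$from[1], 0)
  expect_equal(res2$changes$to[1], 1)
})

test_that("number of acctran changes equals the Fitch step count", {
  set.seed(91)
  for (rep in 1:20) {
    t7 <- simulate_tree(7)
    rooted <- ape::root(t7, outgroup = sample(t7$tip.label, 1),
                        resolve.root = TRUE)
    col <- sample(c("0", "1", "?", "0/1"), 7, replace = TRUE,
                  prob = c(.4, .4, .15, .05))
    names(col) <- t7$tip.label
    res <- acctran_states(rooted, col)
    expect_equal(nrow(res$changes), fitch_steps(t7, col))
    expect_equal(res$steps, fitch_steps(t7, col))
  }
})

test_that("acctran places ambiguous changes rootward of the delayed option", {
  # 5-leaf chain: A out, then (B,(C,(D,E))); column B=0, C=?, D=1, E=1.
  # One change is needed; ACCTRAN pulls it onto the edge into (C,D,E)
  # rather than the deeper edge into (D,E).
  tr <- read_newick(text = "(A,(B,(C,(D,E))));")
  col <- c(A = "0", B = "0", C = "?", D = "1", E = "1")
  res <- acctran_states(tr, col)
  expect_equal(res$steps, 1)
  clades <- mpclad:::.node_clades(tr)
  expect_equal(clades[[res$changes$node[1]]], c("C", "D", "E"))
})

test_that("full-state leaves never generate pendant-edge changes", {
  set.seed(92)
  for (rep in 1:10) {
    t6 <- simulate_tree(6)
    rooted <- ape::root(t6, outgroup = t6$tip.label[1], resolve.root = TRUE)
    col <- sample(c("0", "1"), 6, replace = TRUE)
    names(col) <- t6$tip.label
    full <- sample(names(col), 2)
    col[full] <- "?"
    res <- acctran_states(rooted, col)
    tipnr <- match(full, rooted$tip.label)
    expect_false(any(res$changes$node %in% tipnr))
  }
})

test_that("terminal-branch transformations match autapomorphy classification", {
  m <- coronal_matrix()
  res <- heuristic_search(m, n_addition_replicates = 2, seed = 5)
  apo <- apomorphy_list(res$trees[[1]], m, outgroup = coronal_outgroups())
  cls <- classify_characters(m)
  auto <- cls[cls$status == "autapomorphic", ]
  for (i in seq_len(nrow(auto))) {
    hit <- apo[apo$character == auto$character[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$clade[[1]], auto$autapomorphic_taxon[i])
  }
})

test_that("unambiguous_changes implements intersection semantics", {
  m <- tiny_matrix()
  tr <- ape::root(ape::unroot(quartet_tree()), outgroup = "A",
                  resolve.root = TRUE)
  single <- unambiguous_changes(list(tr), m)
  full <- apomorphy_list(tr, m)
  expect_equal(nrow(single), nrow(full))
  expect_true(all(single$unambiguous))

  # adding a tree lacking the (C,D) bipartition removes that branch's entries
  other <- ape::root(read_newick(text = "((A,C),(B,D));"), outgroup = "A",
                     resolve.root = TRUE)
  both <- unambiguous_changes(list(tr, other), m)
  cd_entries <- vapply(both$clade, function(cl) setequal(cl, c("C", "D")),
                       logical(1))
  expect_false(any(cd_entries))
})
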