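# Fitch scoring, step bounds, ensemble indices and character classification.

test_that("fitch_steps matches forced examples and the brute-force oracle", {
  tr <- quartet_tree()
  expect_equal(fitch_steps(tr, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  expect_equal(fitch_steps(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(fitch_steps(tr, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_error(fitch_steps(tr, c(A = "0", B = "0", C = "1")), "no state")

  set.seed(11)
  for (rep in 1:25) {
    t6 <- simulate_tree(6)
    col <- sample(c("0", "1", "?", "-", "0/1"), 6, replace = TRUE,
                  prob = c(.4, .4, .1, .05, .05))
    names(col) <- t6$tip.label
    expect_equal(fitch_steps(t6, col), brute_force_steps(t6, col),
                 info = paste(col, collapse = ""))
  }
})

test_that("fitch_steps agrees with an independent scorer on random matrices", {
  library(phangorn)
  set.seed(21)
  for (rep in 1:5) {
    tr <- ape::unroot(ape::rtree(10))
    m <- simulate_matrix(tr, 15, change_prob = 0.2, fraction_missing = 0.05)
    masks <- state_masks(m)
    sym <- matrix("?", nrow(masks), ncol(masks))
    sym[masks == 1L] <- "0"
    sym[masks == 2L] <- "1"
    rownames(sym) <- rownames(masks)
    pd <- phangorn::phyDat(sym, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    expect_equal(tree_length(tr, m)$total_length,
                 as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("tree length is invariant to rooting and leaf order", {
  m <- tiny_matrix()
  tr <- read_newick(text = "((A,B),(C,D));")
  base <- tree_length(tr, m)$total_length
  for (og in c("A", "B", "C", "D")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(tree_length(rerooted, m)$total_length, base)
  }
  perm <- read_newick(text = "((D,C),(B,A));")
  expect_equal(tree_length(perm, m)$total_length, base)
})

test_that("relaxing any cell to the full state set never adds steps", {
  set.seed(31)
  for (rep in 1:10) {
    t6 <- simulate_tree(6)
    col <- setNames(sample(c("0", "1"), 6, replace = TRUE), t6$tip.label)
    base <- fitch_steps(t6, col)
    for (i in seq_along(col)) {
      relaxed <- col
      relaxed[i] <- "?"
      expect_lte(fitch_steps(t6, relaxed), base)
    }
  }
})

test_that("min/max step bounds match formulae and exhaustive topologies", {
  col <- c(rep("0", 14), rep("1", 5), "?")
  expect_equal(min_steps(col), 1L)
  expect_equal(max_steps(col), 5L)
  expect_equal(min_steps(rep("0", 6)), 0L)
  expect_equal(max_steps(rep("0", 6)), 0L)
  expect_equal(min_steps(rep("?", 4)), 0L)

  set.seed(41)
  topo7 <- enumerate_topologies(7)
  for (rep in 1:5) {
    col <- sample(c("0", "1", "?"), 7, replace = TRUE, prob = c(.45, .45, .1))
    names(col) <- paste0("t", 1:7)
    worst <- max(vapply(topo7, fitch_steps, integer(1), column = col))
    best <- min(vapply(topo7, fitch_steps, integer(1), column = col))
    expect_equal(max_steps(col), worst)
    expect_equal(min_steps(col), best)
  }
})

test_that("ensemble indices follow their definitions", {
  # homoplasy-free matrix scored on its generating tree: CI = RI = RC = 1
  set.seed(51)
  tr <- simulate_tree(8)
  m <- split_marker_matrix(tr, k = 2)
  sc <- tree_length(tr, m)
  fit <- ensemble_indices(m, sc)
  expect_equal(fit$ci, 1)
  expect_equal(fit$ri, 1)
  expect_equal(fit$rc, 1)
  expect_equal(sc$total_length, fit$min_total)

  # agreement with the independent implementation on the bundled matrix
  library(phangorn)
  mm <- coronal_matrix()
  masks <- state_masks(mm)
  sym <- matrix("?", nrow(masks), ncol(masks))
  sym[masks == 1L] <- "0"
  sym[masks == 2L] <- "1"
  rownames(sym) <- gsub(" ", "_", rownames(masks))
  pd <- phangorn::phyDat(sym, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  set.seed(52)
  tr20 <- ape::rtree(20, tip.label = rownames(sym))
  tr20b <- tr20
  tr20b$tip.label <- rownames(masks)[match(tr20$tip.label, rownames(sym))]
  sc20 <- tree_length(tr20b, mm)
  fit20 <- ensemble_indices(mm, sc20)
  expect_equal(fit20$ci, unname(phangorn::CI(tr20, pd)), tolerance = 1e-12)
  expect_equal(fit20$ri, unname(phangorn::RI(tr20, pd)), tolerance = 1e-12)

  # degenerate: zero observed length reports CI 1 with a warning
  const <- char_matrix(rbind(A = "0", B = "0", C = "0"))
  expect_warning(f0 <- ensemble_indices(const, 0L), "zero")
  expect_equal(f0$ci, 1)
})

test_that("character classification separates constant/autapomorphic/informative", {
  m <- char_matrix(rbind(
    A = c("0", "0", "0", "?"),
    B = c("0", "0", "1", "?"),
    C = c("1", "0", "1", "?"),
    D = c("1", "0", "1", "?")
  ))
  cls <- classify_characters(m)
  expect_equal(cls$status, c("informative", "constant", "autapomorphic",
                             "constant"))
  expect_equal(cls$autapomorphic_taxon[3], "A")

  cls_fix <- classify_characters(coronal_matrix())
  expect_equal(sum(cls_fix$status == "informative"), 16)
  expect_equal(sort(cls_fix$character[cls_fix$autapomorphic_taxon ==
                                        "Oikopleura dioica" &
                                        !is.na(cls_fix$autapomorphic_taxon)]),
               c(5L, 11L))
  expect_equal(cls_fix$character[cls_fix$autapomorphic_taxon ==
                                   "Diplosoma listerianum" &
                                   !is.na(cls_fix$autapomorphic_taxon)], 10L)
})

test_that("character report ties steps, bounds and indices together", {
  m <- coronal_matrix()
  tr <- heuristic_search(m, n_addition_replicates = 2, seed = 3)$trees[[1]]
  rep <- character_report(m, tr)
  expect_equal(nrow(rep), 19)
  expect_true(all(rep$steps >= rep$min_steps))
  expect_true(all(rep$steps <= rep$max_steps))
  expect_true(all(rep$ci[rep$steps > 0] <= 1))
  sc <- tree_length(tr, m)
  expect_equal(sum(rep$steps), sc$total_length)
})
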