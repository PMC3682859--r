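# Character-matrix container, NEXUS round trips, Newick wrappers, pruning.

test_that("symbol mapping and cell source tags survive a NEXUS round trip", {
  m <- char_matrix(rbind(
    A = c("0", "?", "0/1"),
    B = c("1", "-", "0"),
    C = c("1", "1", "1")
  ))
  expect_equal(unname(m$cells[1, ]), c(1L, 3L, 3L))
  expect_equal(unname(m$tags[1, ]), c("resolved", "missing", "ambiguous"))
  expect_equal(unname(m$tags[2, 2]), "inapplicable")

  doc <- write_nexus(m)
  expect_match(doc, "NCHAR=3")
  expect_match(doc, "NTAX=3")
  expect_match(doc, "\\(01\\)")
  m2 <- read_nexus(text = doc)
  expect_true(isTRUE(all.equal(m, m2)))
  # writer is a fixed point: write(read(write(m))) == write(m)
  expect_identical(write_nexus(m2), doc)
})

test_that("NEXUS reader rejects malformed documents with clear errors", {
  m <- tiny_matrix()
  doc <- write_nexus(m)
  # ragged row: drop one state from taxon B
  broken <- sub("('B')(\\s+)011", "\\1\\201", doc)
  expect_error(read_nexus(text = broken), "ragged.*'B'")
  # undeclared symbol
  broken2 <- sub("011", "0x1", doc)
  expect_error(read_nexus(text = broken2), "undeclared state symbol 'x'")
  # zero characters
  zero <- paste0("#NEXUS\nBEGIN CHARACTERS;\nDIMENSIONS NCHAR=0;\n",
                 "MATRIX\n;\nEND;\n")
  expect_error(read_nexus(text = zero), "zero characters")
  expect_error(read_nexus(text = "just text"), "NEXUS")
})

test_that("the bundled matrix matches its printed source", {
  m <- coronal_matrix()
  expect_equal(n_taxa(m), 20)
  expect_equal(n_characters(m), 19)
  # spot checks of individual printed cells
  expect_equal(unname(m$cells["Oikopleura dioica", 6]), 3L)
  expect_equal(unname(m$tags["Oikopleura dioica", 6]), "ambiguous")
  expect_equal(unname(m$cells["Branchiostoma floridae", 19]), 1L) # state 0
  expect_equal(unname(m$tags["Pyrosoma atlanticum", 15]), "missing")
  expect_equal(unname(m$tags["Oikopleura dioica", 19]), "missing")
  expect_equal(unname(m$tags["Botryllus schlosseri", 5]), "inapplicable")
  # hand tally: six taxa carry state 0 for character 1
  expect_equal(sum(m$cells[, 1] == 1L), 6)
  # hand tallies of per-column unambiguous state counts (characters 1-4)
  expect_equal(unname(colSums(m$cells == 2L)[1:4]), c(14, 12, 4, 8))
  expect_equal(unname(colSums(m$cells == 3L)), # full-state cells per column
               c(0, 0, 0, 0, 8, 1, 8, 8, 11, 14, 12, 0, 0, 0, 5, 2, 0, 4, 1))
  # character table carries the published definitions
  expect_match(m$characters$definition[4], "more than two cilia")
  # the bundled NEXUS file reproduces the programmatic constant exactly
  f <- system.file("extdata", "coronal_organ_matrix.nex", package = "mpclad")
  expect_true(isTRUE(all.equal(m, read_nexus(f))))
})

test_that("pruning removes rows only and guards degenerate input", {
  m <- coronal_matrix()
  expect_true(isTRUE(all.equal(m, prune_taxa(m, character(0)))))
  m3 <- tiny_matrix()
  p <- prune_taxa(m3, "D")
  expect_equal(taxa_labels(p), c("A", "B", "C"))
  expect_equal(n_characters(p), 3)
  expect_error(prune_taxa(m3, "nope"), "unknown taxon")
  expect_error(prune_taxa(m3, c("A", "B", "C")), "fewer than 2")
})

test_that("newick wrappers validate input and preserve bipartitions", {
  tr <- read_newick(text = "(A,B,(C,D));")
  bp <- bipartitions(tr)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$clade[[1]], c("C", "D"))
  expect_error(read_newick(text = "(A,(A,B));"), "duplicate leaf label")
  expect_error(read_newick(text = "((A,B);"), "unbalanced")
  # round trip of a random 10-leaf tree preserves the split set
  set.seed(42)
  t10 <- simulate_tree(10)
  t10b <- read_newick(text = write_newick(t10))
  expect_equal(topo_key(t10), topo_key(t10b))
})
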