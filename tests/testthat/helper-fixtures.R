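# Shared fixture builders and independent oracles for the test suite.

# the exact search of the bundled matrix is used by several tests; run it
# once per session
.shared <- new.env(parent = emptyenv())
fixture_search <- function() {
  if (is.null(.shared$res)) {
    .shared$res <- branch_and_bound(coronal_matrix())
  }
  .shared$res
}

# tiny matrices built in code
tiny_matrix <- function() {
  char_matrix(rbind(
    A = c("0", "0", "1"),
    B = c("0", "1", "1"),
    C = c("1", "1", "0"),
    D = c("1", "?", "0")
  ))
}

quartet_tree <- function() read_newick(text = "((A,B),(C,D));")

# brute-force Fitch oracle: minimum changes over every explicit assignment of
# states to internal nodes (and to leaves whose state set is {0,1})
brute_force_steps <- function(tree, column) {
  masks <- if (is.character(column)) {
    mpclad:::.sym_to_mask(stats::setNames(column, names(column)))
  } else column
  names(masks) <- names(column)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  fixed <- rep(NA_integer_, nnode)
  free <- integer()
  for (i in seq_len(ntip)) {
    mk <- masks[[tree$tip.label[i]]]
    if (mk == 1L) fixed[i] <- 0L
    else if (mk == 2L) fixed[i] <- 1L
    else free <- c(free, i)
  }
  free <- c(free, (ntip + 1):nnode)
  best <- Inf
  for (code in 0:(2^length(free) - 1)) {
    st <- fixed
    st[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
    len <- sum(st[edge[, 1]] != st[edge[, 2]])
    if (len < best) best <- len
  }
  as.integer(best)
}

# canonical string identity of an unrooted topology (sorted split keys)
topo_key <- function(tree) {
  paste(sort(vapply(mpclad:::.tree_splits(tree), mpclad:::.split_key,
                    character(1))), collapse = "||")
}

# matrix in which each of a tree's non-trivial splits is marked by `k` clean
# binary characters (homoplasy-free by construction)
split_marker_matrix <- function(tree, k = 1) {
  splits <- mpclad:::.tree_splits(tree)
  tips <- tree$tip.label
  cols <- lapply(splits, function(s) ifelse(tips %in% s, "1", "0"))
  x <- do.call(cbind, rep(cols, each = k))
  rownames(x) <- tips
  char_matrix(x)
}
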