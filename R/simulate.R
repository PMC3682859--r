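# Synthetic data: binary characters evolved on a known tree by a symmetric
# per-edge flip process (two-state Mk-like), with optional injection of
# missing / inapplicable / ambiguous cells, plus an exhaustive-enumeration
# known-answer oracle for the search routines.

#' Simulate a uniform random unrooted binary tree
#'
#' Built by sequential random edge attachment (each new leaf is attached to
#' an edge drawn uniformly), which yields the uniform distribution over
#' unrooted binary topologies.
#'
#' @param n_taxa number of leaves (>= 4); labels are `t1..tn`.
#' @param seed optional integer seed.
#' @return an unrooted binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 4)
  if (!is.null(seed)) set.seed(seed)
  n <- n_taxa
  # leaves 1..n, internal nodes n+1 ..; edge list grown by random insertion
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                  ncol = 2, byrow = TRUE)
  for (k in 4:n) {
    node <- n + k - 2L
    e <- sample.int(nrow(edges), 1)
    old <- edges[e, ]
    edges[e, ] <- c(old[1], node)
    edges <- rbind(edges, c(node, old[2]), c(node, k))
  }
  # serialise via adjacency -> newick
  adj <- vector("list", max(edges))
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
  }
  build <- function(u, par) {
    if (u <= n) return(paste0("t", u))
    kids <- setdiff(adj[[u]], par)
    paste0("(", paste(vapply(kids, build, character(1), par = u),
                      collapse = ","), ")")
  }
  root <- adj[[1]][1]
  ape::read.tree(text = paste0(build(root, -1L), ";"))
}

#' Simulate a binary character matrix on a tree
#'
#' Each character starts from a uniformly drawn root state and flips along
#' every edge independently with probability `change_prob`. Afterwards,
#' cells are overwritten uniformly at random as missing (`?`), inapplicable
#' (`-`) or ambiguous (`0/1`) at the given fractions.
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @param n_characters number of characters to simulate.
#' @param change_prob per-edge state-flip probability (scalar).
#' @param fraction_missing,fraction_inapplicable,fraction_ambiguous cell
#'   corruption fractions; their sum must be below 1.
#' @param seed optional integer seed.
#' @return a [char_matrix] whose taxa are the tree's leaves; the generating
#'   tree is attached as attribute `"true_tree"`.
#' @export
simulate_matrix <- function(tree, n_characters, change_prob = 0.05,
                            fraction_missing = 0, fraction_inapplicable = 0,
                            fraction_ambiguous = 0, seed = NULL) {
  stopifnot(n_characters >= 1, change_prob >= 0, change_prob <= 1)
  fr <- c(fraction_missing, fraction_inapplicable, fraction_ambiguous)
  stopifnot(all(fr >= 0), all(fr < 1), sum(fr) < 1)
  if (!is.null(seed)) set.seed(seed)
  # evolve over the unrooted tree's 2n-3 edges, starting from leaf 1, so
  # every edge carries the flip probability exactly once (rooting a
  # symmetric flip process inside an edge would double that edge's rate)
  phy <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(phy$tip.label)
  edge <- phy$edge
  nnode <- max(edge)
  adj <- vector("list", nnode)
  for (r in seq_len(nrow(edge))) {
    adj[[edge[r, 1]]] <- c(adj[[edge[r, 1]]], edge[r, 2])
    adj[[edge[r, 2]]] <- c(adj[[edge[r, 2]]], edge[r, 1])
  }
  # edge order from a DFS rooted at leaf 1
  path <- matrix(0L, nrow(edge), 2)
  stk <- 1L
  seen <- logical(nnode)
  seen[1] <- TRUE
  k <- 0L
  while (length(stk)) {
    u <- stk[length(stk)]
    stk <- stk[-length(stk)]
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        k <- k + 1L
        path[k, ] <- c(u, v)
        stk <- c(stk, v)
      }
    }
  }
  x <- matrix("0", ntip, n_characters)
  for (j in seq_len(n_characters)) {
    st <- integer(nnode)
    st[1] <- rbinom(1, 1, 0.5)
    for (r in seq_len(nrow(path))) {
      flip <- runif(1) < change_prob
      st[path[r, 2]] <- if (flip) 1L - st[path[r, 1]] else st[path[r, 1]]
    }
    x[, j] <- as.character(st[seq_len(ntip)])
  }
  ncell <- length(x)
  n_miss <- round(fraction_missing * ncell)
  n_inap <- round(fraction_inapplicable * ncell)
  n_ambi <- round(fraction_ambiguous * ncell)
  hit <- sample.int(ncell, n_miss + n_inap + n_ambi)
  x[hit[seq_len(n_miss)]] <- "?"
  x[hit[n_miss + seq_len(n_inap)]] <- "-"
  x[hit[n_miss + n_inap + seq_len(n_ambi)]] <- "0/1"
  rownames(x) <- phy$tip.label
  m <- char_matrix(x)
  attr(m, "true_tree") <- tree
  m
}

#' Known-answer fixture: matrix plus its complete optimal tree set
#'
#' Simulates a matrix on a random tree and computes its full set of
#' most-parsimonious trees by scoring every unrooted binary topology --
#' the exhaustive oracle against which the search routines are tested.
#' Guarded to 9 taxa.
#'
#' @param n_taxa number of leaves (4..9).
#' @param n_characters number of simulated characters.
#' @param seed integer seed.
#' @param ... further arguments to [simulate_matrix()].
#' @return list with `matrix` (a [char_matrix]), `best_length`, and `trees`
#'   (`multiPhylo` of all optimal topologies).
#' @export
known_answer_fixture <- function(n_taxa, n_characters, seed, ...) {
  if (n_taxa > 9) abort("known-answer oracle guarded to 9 taxa")
  tr <- simulate_tree(n_taxa, seed = seed)
  m <- simulate_matrix(tr, n_characters, ...)
  topo <- enumerate_topologies(taxa_labels(m))
  lens <- vapply(topo, function(t) tree_length(t, m)$total_length, integer(1))
  best <- min(lens)
  trees <- topo[lens == best]
  class(trees) <- "multiPhylo"
  list(matrix = m, best_length = best, trees = trees)
}
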