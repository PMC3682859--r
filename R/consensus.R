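# Consensus trees over bipartitions: strict (100%) and majority rule
# (> 50%), with per-edge frequencies, plus outgroup rooting for display.

# non-trivial splits of one tree, each stored as the sorted label set of the
# side NOT containing the reference taxon (lexicographically smallest label)
.tree_splits <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  n <- length(tips)
  if (is.null(ref)) ref <- min(tips)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- max(edge)
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- tips[i]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    below[[p]] <- c(below[[p]], below[[edge[r, 2]]])
  }
  out <- list()
  for (r in seq_len(nrow(edge))) {
    side <- below[[edge[r, 2]]]
    k <- length(side)
    if (k < 2 || k > n - 2) next
    if (ref %in% side) side <- setdiff(tips, side)
    out[[length(out) + 1]] <- sort(side)
  }
  unique(out)
}

.split_key <- function(split) paste(split, collapse = "\x1f")

.split_label <- function(split) paste(split, collapse = ", ")

# frequency table of splits over a tree set
.split_freqs <- function(trees) {
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!setequal(trees[[i]]$tip.label, tips)) {
      abort(sprintf("tree %d has a different leaf set", i))
    }
  }
  ref <- min(tips)
  splits <- purrr::map(trees, .tree_splits, ref = ref)
  keys <- lapply(splits, function(s) vapply(s, .split_key, character(1)))
  tab <- table(unlist(keys))
  all_splits <- unlist(splits, recursive = FALSE)
  first <- !duplicated(vapply(all_splits, .split_key, character(1)))
  uniq <- all_splits[first]
  names(uniq) <- vapply(uniq, .split_key, character(1))
  tibble(
    key = names(tab),
    clade = unname(uniq[names(tab)]),
    count = as.integer(tab),
    frequency = 100 * as.integer(tab) / length(trees)
  )
}

# build a (possibly multifurcating) consensus phylo from mutually compatible
# clades (sides excluding the reference taxon), labelling internal nodes
# with integer-rounded frequencies
.build_consensus_tree <- function(tips, clades, freqs) {
  ref <- min(tips)
  others <- setdiff(tips, ref)
  o <- order(-lengths(clades))
  clades <- clades[o]
  freqs <- freqs[o]
  k <- length(clades)
  parent <- rep(0L, k) # 0 = top level
  if (k > 1) {
    for (i in seq_len(k)) {
      for (j in seq_len(i - 1)) {
        if (all(clades[[i]] %in% clades[[j]])) parent[i] <- j # smallest last
      }
    }
  }
  leaf_parent <- vapply(others, function(lf) {
    holders <- which(vapply(clades, function(cl) lf %in% cl, logical(1)))
    if (length(holders) == 0) 0L else holders[length(holders)]
  }, integer(1))
  # build with placeholder leaf names (labels may contain spaces or quotes,
  # which newick parsers handle inconsistently), then restore
  code <- function(x) paste0("x", match(x, tips), recycle0 = TRUE)
  build <- function(i) {
    sub_cl <- which(parent == i)
    sub_lf <- others[leaf_parent == i]
    parts <- c(vapply(sub_cl, build, character(1)), code(sub_lf))
    if (i == 0L) {
      paste0("(", paste(c(code(ref), parts), collapse = ","), ");")
    } else {
      paste0("(", paste(parts, collapse = ","), ")", round(freqs[i]))
    }
  }
  tree <- ape::read.tree(text = build(0L))
  tree$tip.label <- tips[as.integer(sub("^x", "", tree$tip.label))]
  tree
}

.new_consensus <- function(tree, splits, method, threshold, n_input) {
  structure(
    list(tree = tree, splits = splits, method = method,
         threshold = threshold, n_input = n_input),
    class = "consensus_tree"
  )
}

#' Bipartitions of a tree
#'
#' The non-trivial splits induced by the internal edges of a tree, each
#' reported as the taxon set on the side excluding the reference taxon
#' (the lexicographically smallest leaf label). An unrooted binary tree on
#' n leaves has exactly n - 3 of them.
#'
#' @param tree a `phylo` with at least 4 leaves.
#' @return tibble with columns `bipartition` (display label) and `clade`
#'   (list column of taxon sets).
#' @export
bipartitions <- function(tree) {
  if (length(tree$tip.label) < 4) abort("bipartitions need at least 4 leaves")
  sp <- .tree_splits(tree)
  tibble(
    bipartition = vapply(sp, .split_label, character(1)),
    clade = sp
  )
}

#' Strict and majority-rule consensus trees
#'
#' `strict_consensus()` retains exactly the bipartitions present in every
#' input tree; `majority_rule()` those present in more than `threshold`
#' percent (plain majority rule: no compatible-minority grafting).
#' Frequencies are attached to internal nodes as integer-rounded
#' percentages; full precision is kept in the `splits` table.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) over a common leaf set.
#' @param threshold retention threshold in percent (strictly greater-than).
#' @return an object of class `consensus_tree`: list with `tree` (a `phylo`,
#'   possibly multifurcating, node labels = rounded frequencies), `splits`
#'   (tibble: `bipartition`, `clade`, `count`, `frequency`), `method`,
#'   `threshold` and `n_input`.
#' @examples
#' res <- branch_and_bound(coronal_matrix())
#' cons <- majority_rule(res$trees)
#' cons$splits
#' @export
strict_consensus <- function(trees) {
  .consensus_impl(trees, 100, "strict")
}

#' @rdname strict_consensus
#' @export
majority_rule <- function(trees, threshold = 50) {
  stopifnot(threshold >= 50, threshold <= 100)
  .consensus_impl(trees, threshold, "majority-rule")
}

.consensus_impl <- function(trees, threshold, method) {
  trees <- .as_tree_list(trees)
  if (length(trees) == 0) abort("empty tree set")
  fr <- .split_freqs(trees)
  keep <- if (method == "strict") fr$count == length(trees)
          else fr$frequency > threshold
  kept <- fr[keep, , drop = FALSE]
  tips <- sort(trees[[1]]$tip.label)
  tree <- .build_consensus_tree(tips, kept$clade, kept$frequency)
  splits <- tibble(
    bipartition = vapply(kept$clade, .split_label, character(1)),
    clade = kept$clade,
    count = kept$count,
    frequency = kept$frequency
  )
  splits <- splits[order(-splits$frequency, lengths(splits$clade)), ]
  .new_consensus(tree, splits, method, threshold, length(trees))
}

.as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(all(vapply(trees, inherits, logical(1), "phylo")))
  trees
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree:%s> of %d trees; %d retained bipartition(s)\n",
              x$method, x$n_input, nrow(x$splits)))
  print(x$splits, n = 8)
  invisible(x)
}

#' @export
tidy.consensus_tree <- function(x, ...) x$splits

#' Root a tree between outgroups and ingroup for display
#'
#' Roots on the edge separating the smallest clade containing all outgroup
#' taxa from the rest. When the outgroups do not form a clade the tree is
#' rooted on the pendant edge of the first outgroup, with a warning.
#' Rooting is display-only: bipartitions and their frequencies are
#' unchanged.
#'
#' @param x a `consensus_tree` or a `phylo`.
#' @param outgroup character vector of outgroup taxon labels.
#' @return an object of the same class, rooted.
#' @export
root_for_display <- function(x, outgroup) {
  if (inherits(x, "consensus_tree")) {
    x$tree <- root_for_display(x$tree, outgroup)
    return(x)
  }
  tree <- x
  outgroup <- intersect(outgroup, tree$tip.label)
  if (length(outgroup) == 0) abort("no outgroup taxa present in the tree")
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(outgroup) == 1) {
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  # does any edge separate the outgroups from the ingroup? (checked on the
  # split set, independent of where the tree's arbitrary base sits)
  has_edge <- length(ingroup) == 1 ||
    any(vapply(.tree_splits(tree, ref = ingroup[1]), setequal, logical(1),
               y = outgroup))
  if (has_edge) {
    # one of the two sides is a clade as seen from the current base
    out <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                    error = function(e) NULL)
    if (is.null(out)) {
      out <- ape::root(tree, outgroup = ingroup, resolve.root = TRUE)
    }
    return(out)
  }
  warn("outgroup is not a clade; rooting on the first outgroup's pendant edge")
  ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
}
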