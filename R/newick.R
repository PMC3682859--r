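# Newick tree I/O: thin wrappers over ape with the validation the rest of
# the package relies on (balanced parentheses, unique leaf labels).

#' Read and write Newick trees
#'
#' `read_newick()` parses a Newick string (or file) into an [ape::phylo]
#' object, rejecting unbalanced parentheses and duplicate leaf labels.
#' `write_newick()` serialises a tree (or list of trees) back to Newick;
#' unrooted trees are written with the conventional trifurcating base.
#' A parse-write-parse cycle preserves the bipartition set.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text a Newick string.
#' @return `read_newick()`: a `phylo` (or `multiPhylo` when the input holds
#'   several trees); `write_newick()`: a character vector of Newick strings,
#'   invisibly when written to `file`.
#' @examples
#' tr <- read_newick(text = "(A,B,(C,D));")
#' write_newick(tr)
#' @export
read_newick <- function(file = NULL, text = NULL) {
  txt <- if (!is.null(text)) text else paste(readLines(file), collapse = "\n")
  bare <- gsub("'[^']*'", "", txt)
  op <- lengths(regmatches(bare, gregexpr("(", bare, fixed = TRUE)))
  cl <- lengths(regmatches(bare, gregexpr(")", bare, fixed = TRUE)))
  if (sum(op) != sum(cl)) {
    abort(sprintf("unbalanced parentheses in Newick input (%d '(' vs %d ')')",
                  sum(op), sum(cl)))
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) abort("could not parse Newick input")
  check_one <- function(t) {
    if (anyDuplicated(t$tip.label)) {
      abort(sprintf("duplicate leaf label: %s",
                    t$tip.label[duplicated(t$tip.label)][1]))
    }
    t
  }
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, check_one)
  } else {
    check_one(tr)
  }
  tr
}

#' @param tree a `phylo` or `multiPhylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  out <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# parse the t<k>-labelled newicks produced by the C++ engines and restore
# taxon labels
.trees_from_engine <- function(newicks, taxa) {
  trees <- lapply(newicks, function(s) {
    tr <- ape::read.tree(text = s)
    idx <- as.integer(sub("^t", "", tr$tip.label))
    tr$tip.label <- taxa[idx]
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

# engine-facing edge matrix of an unrooted binary tree whose tips are
# renumbered to match a reference taxon ordering
.edge_for_engine <- function(tree, taxa) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) {
    abort(sprintf("tree leaf '%s' not among the matrix taxa",
                  tree$tip.label[which(is.na(idx))[1]]))
  }
  n <- length(taxa)
  if (length(idx) != n) abort("tree and matrix taxon sets differ")
  edge <- tree$edge
  tipmask <- edge <= length(tree$tip.label)
  edge[tipmask] <- idx[edge[tipmask]]
  edge
}
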