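# Tree search: exact branch-and-bound enumeration of every most-parsimonious
# tree, and a heuristic search (random stepwise addition + TBR swapping,
# retaining all optimal trees) used on its own and inside the jackknife.

.new_mp_search <- function(best_length, trees, m, mode, diagnostics) {
  sc <- tree_length(trees[[1]], m)
  fit <- ensemble_indices(m, structure(
    list(total_length = best_length,
         per_character_steps = sc$per_character_steps),
    class = "parsimony_score"))
  structure(
    list(best_length = best_length, trees = trees, n_trees = length(trees),
         fit = fit, mode = mode, taxa = taxa_labels(m),
         diagnostics = diagnostics),
    class = "mp_search"
  )
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("<mp_search:%s> %d optimal tree(s) of length %d\n",
              x$mode, x$n_trees, x$best_length))
  cat(sprintf("  CI %.2f  RI %.2f  RC %.2f\n",
              x$fit$ci, x$fit$ri, x$fit$rc))
  invisible(x)
}

#' Enumerate all unrooted binary topologies
#'
#' Yields every distinct unrooted binary tree over the given leaves, used as
#' the exhaustive oracle for the search routines. The count grows as the
#' double factorial (2n-5)!!, so enumeration is guarded to 10 leaves.
#'
#' @param taxa leaf labels, or a single integer n (labels become `t1..tn`).
#' @return a `multiPhylo` of (2n-5)!! trees.
#' @examples
#' length(enumerate_topologies(5)) # 15
#' @export
enumerate_topologies <- function(taxa) {
  if (is.numeric(taxa) && length(taxa) == 1) {
    taxa <- paste0("t", seq_len(taxa))
  }
  n <- length(taxa)
  if (n < 3 || n > 10) {
    count <- if (n >= 3) prod(seq(2 * n - 5, 1, by = -2)) else 0
    abort(sprintf(
      "topology enumeration is guarded to 3..10 leaves (n = %d would give %s trees)",
      n, format(count, big.mark = ",")))
  }
  .trees_from_engine(enumerate_cpp(n), taxa)
}

#' Exact search for all most-parsimonious trees by branch and bound
#'
#' Enumerates taxon-addition sequences with an admissible lower bound so
#' that the complete set of optimal unrooted binary topologies is found
#' without exhaustive enumeration. Taxa are added in a "max-min" order (the
#' next taxon is the one whose best insertion into a greedily grown
#' reference tree costs most); the reference tree also seeds the upper
#' bound. The result is deterministic.
#'
#' @param m a [char_matrix] with at least 3 taxa.
#' @param upper_bound optional known tree length used to seed the bound
#'   (e.g. from [heuristic_search()]); it must be attainable.
#' @param max_trees cap on the number of optimal trees retained.
#' @return an object of class `mp_search`: fields `best_length`, `trees`
#'   (`multiPhylo`), `n_trees`, `fit` ([ensemble_indices()] of the optimum),
#'   `mode`, and search `diagnostics`.
#' @examples
#' res <- branch_and_bound(coronal_matrix())
#' res$best_length
#' @export
branch_and_bound <- function(m, upper_bound = NULL, max_trees = 100000L) {
  if (n_taxa(m) < 3) abort("need at least 3 taxa")
  t0 <- proc.time()[["elapsed"]]
  r <- bab_cpp(state_masks(m),
               if (is.null(upper_bound)) .Machine$integer.max
               else as.integer(upper_bound),
               as.integer(max_trees))
  if (isTRUE(r$overflow)) {
    warn(sprintf("more than %d optimal trees; archive truncated", max_trees))
  }
  trees <- .trees_from_engine(r$trees, taxa_labels(m))
  .new_mp_search(
    r$best_length, trees, m, "branch-and-bound",
    list(nodes_expanded = r$nodes_expanded, bound_updates = r$bound_updates,
         addition_order = taxa_labels(m)[r$order],
         reference_length = r$reference_length,
         elapsed = proc.time()[["elapsed"]] - t0)
  )
}

#' Heuristic search: random stepwise addition with TBR swapping
#'
#' For each addition-sequence replicate the taxa are added in random order,
#' each placed on its cheapest edge; the resulting tree is then improved by
#' first-improvement tree bisection-reconnection (TBR) swapping. All
#' distinct topologies tying the best length are archived, and swapping
#' restarts from every archived tree until the set is closed. Results from
#' all replicates are pooled and deduplicated by bipartition set.
#'
#' @param m a [char_matrix] with at least 4 taxa (and at most 64).
#' @param n_addition_replicates number of random addition sequences.
#' @param seed integer seed for the search's random number stream.
#' @param max_trees cap on the archived optimal trees.
#' @return an `mp_search` (see [branch_and_bound()]).
#' @export
heuristic_search <- function(m, n_addition_replicates = 10, seed = 1,
                             max_trees = 1000L) {
  stopifnot(n_addition_replicates >= 1)
  if (n_taxa(m) < 4) abort("heuristic search needs at least 4 taxa")
  t0 <- proc.time()[["elapsed"]]
  r <- heuristic_cpp(state_masks(m), as.integer(n_addition_replicates),
                     as.integer(seed), as.integer(max_trees))
  trees <- .trees_from_engine(r$trees, taxa_labels(m))
  .new_mp_search(
    r$best_length, trees, m, "heuristic",
    list(trees_scored = r$trees_scored, replicate_best = r$replicate_best,
         seed = seed, hit_max_trees = r$hit_max_trees,
         elapsed = proc.time()[["elapsed"]] - t0)
  )
}

#' TBR neighbourhood of a tree
#'
#' All distinct topologies obtained by bisecting one edge of the tree and
#' reconnecting the two pieces across any pair of edges. The input topology
#' itself is excluded.
#'
#' @param tree an unrooted binary `phylo` with at least 4 leaves.
#' @return a `multiPhylo`.
#' @export
tbr_neighbors <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n < 4) abort("TBR needs at least 4 leaves")
  edge <- .edge_for_engine(tree, tree$tip.label)
  .trees_from_engine(tbr_cpp(edge, n), tree$tip.label)
}

#' @export
glance.mp_search <- function(x, ...) {
  tibble(
    best_length = x$best_length,
    n_trees = x$n_trees,
    ci = x$fit$ci,
    ri = x$fit$ri,
    rc = x$fit$rc,
    min_total = x$fit$min_total,
    max_total = x$fit$max_total,
    mode = x$mode
  )
}

#' @param m the character matrix the search was run on; when supplied the
#'   per-character report is computed on the first optimal tree.
#' @export
tidy.mp_search <- function(x, m = NULL, ...) {
  if (is.null(m)) {
    abort("tidy.mp_search needs the character matrix: tidy(res, m = matrix)")
  }
  character_report(m, x$trees[[1]])
}
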