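# Jackknife support: characters are deleted at random, the reduced matrix is
# searched heuristically, and a bipartition is credited to a replicate when
# it appears in the strict consensus of that replicate's optimal trees.

#' Jackknife support by random character deletion
#'
#' For each replicate every character is deleted independently with
#' probability `deletion` (redrawing if all characters would be deleted),
#' the reduced matrix is analysed with [heuristic_search()], and a
#' bipartition is supported by the replicate if it occurs in the strict
#' consensus of the replicate's optimal trees (set `weighting =
#' "fractional"` to credit instead the fraction of optimal trees containing
#' it). Support is the percentage of supporting replicates. Internally taxa
#' are processed in sorted label order, so support values do not depend on
#' the row order of the matrix.
#'
#' @param m a [char_matrix].
#' @param replicates number of jackknife replicates.
#' @param deletion per-character deletion probability (0 < deletion < 1).
#' @param n_addition_replicates addition-sequence replicates per search.
#' @param seed integer seed governing deletions and searches.
#' @param max_trees archived-tree cap per replicate search.
#' @param fixed_count delete exactly this many characters per replicate
#'   instead of the independent-deletion model (optional).
#' @param weighting `"strict"` (default) or `"fractional"`.
#' @return object of class `jackknife_support`: list with `support` (tibble:
#'   `bipartition`, `clade`, `support`), `replicates` (log tibble), and the
#'   configuration.
#' @export
jackknife <- function(m, replicates = 1000, deletion = 0.30,
                      n_addition_replicates = 10, seed = 1,
                      max_trees = 200L, fixed_count = NULL,
                      weighting = c("strict", "fractional")) {
  stopifnot(replicates >= 1, deletion > 0, deletion < 1)
  weighting <- match.arg(weighting)
  nc <- n_characters(m)
  # canonical taxon order: support is then invariant to matrix row order
  ord <- order(taxa_labels(m))
  masks_all <- state_masks(m)[ord, , drop = FALSE]
  taxa <- taxa_labels(m)[ord]
  ref <- min(taxa)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  credit <- list()
  log_rep <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    repeat {
      del <- if (is.null(fixed_count)) {
        runif(nc) < deletion
      } else {
        seq_len(nc) %in% sample.int(nc, fixed_count)
      }
      if (!all(del)) break
    }
    sub <- masks_all[, !del, drop = FALSE]
    search_seed <- sample.int(.Machine$integer.max, 1)
    h <- heuristic_cpp(sub, as.integer(n_addition_replicates),
                       as.integer(search_seed), as.integer(max_trees))
    trees <- .trees_from_engine(h$trees, taxa)
    if (weighting == "strict") {
      splits <- if (length(trees) == 1) {
        .tree_splits(trees[[1]], ref = ref)
      } else {
        fr <- .split_freqs(trees)
        fr$clade[fr$count == length(trees)]
      }
      w <- rep(1, length(splits))
    } else {
      fr <- .split_freqs(trees)
      splits <- fr$clade
      w <- fr$count / length(trees)
    }
    keys <- vapply(splits, .split_key, character(1))
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (is.null(credit[[k]])) {
        credit[[k]] <- list(clade = splits[[i]], w = w[i])
      } else {
        credit[[k]]$w <- credit[[k]]$w + w[i]
      }
    }
    log_rep[[r]] <- tibble(replicate = r, n_deleted = sum(del),
                           best_length = h$best_length,
                           n_trees = length(trees),
                           hit_max_trees = h$hit_max_trees)
  }
  support <- tibble(
    bipartition = vapply(credit, function(x) .split_label(x$clade),
                         character(1)),
    clade = lapply(credit, function(x) x$clade),
    support = vapply(credit, function(x) 100 * x$w / replicates, numeric(1))
  )
  support <- support[order(-support$support, lengths(support$clade)), ]
  structure(
    list(support = support, replicates = dplyr::bind_rows(log_rep),
         config = list(replicates = replicates, deletion = deletion,
                       n_addition_replicates = n_addition_replicates,
                       seed = seed, max_trees = max_trees,
                       fixed_count = fixed_count, weighting = weighting)),
    class = "jackknife_support"
  )
}

#' @export
print.jackknife_support <- function(x, ...) {
  cat(sprintf(
    "<jackknife_support> %d replicates, %.0f%% character deletion\n",
    x$config$replicates, 100 * x$config$deletion))
  print(x$support, n = 10)
  invisible(x)
}

#' @export
tidy.jackknife_support <- function(x, ...) x$support

#' Attach jackknife support to a consensus tree
#'
#' Adds, for every retained bipartition of the consensus, the jackknife
#' percentage alongside the consensus frequency; node labels become
#' `"frequency/jackknife"`. Bipartitions without a support entry are
#' annotated `"<50"`. The operation is idempotent.
#'
#' @param consensus a `consensus_tree`.
#' @param support a `jackknife_support` over the same taxon set.
#' @return the annotated `consensus_tree` (splits gain a `jackknife`
#'   column).
#' @export
annotate_support <- function(consensus, support) {
  stopifnot(inherits(consensus, "consensus_tree"),
            inherits(support, "jackknife_support"))
  sk <- vapply(support$support$clade, .split_key, character(1))
  ck <- vapply(consensus$splits$clade, .split_key, character(1))
  jk <- support$support$support[match(ck, sk)]
  consensus$splits$jackknife <- jk
  lab_num <- ifelse(is.na(jk), "<50", sprintf("%.0f", jk))
  # rebuild node labels as freq/jack via a fresh consensus newick
  tree <- consensus$tree
  if (!is.null(tree$node.label)) {
    # map each internal node to its split key
    tips <- tree$tip.label
    ref <- min(tips)
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    nnode <- max(edge)
    below <- vector("list", nnode)
    for (i in seq_along(tips)) below[[i]] <- tips[i]
    for (r in seq_len(nrow(edge))) {
      below[[edge[r, 1]]] <- c(below[[edge[r, 1]]], below[[edge[r, 2]]])
    }
    ntip <- length(tips)
    labs <- tree$node.label
    for (nd in (ntip + 1):nnode) {
      side <- below[[nd]]
      k <- length(side)
      if (k < 2 || k > ntip - 2) next
      if (ref %in% side) side <- setdiff(tips, side)
      key <- .split_key(sort(side))
      i <- match(key, ck)
      if (!is.na(i)) {
        labs[nd - ntip] <- sprintf("%.0f/%s", consensus$splits$frequency[i],
                                   lab_num[i])
      }
    }
    tree$node.label <- labs
    consensus$tree <- tree
  }
  consensus
}
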