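# ACCTRAN ancestral-state reconstruction. A unit-cost dynamic programme
# (leaf state sets allowed) gives the per-node cost of fixing each state;
# the top-down pass then prefers a change over retention whenever both are
# equally parsimonious, placing changes as close to the root as possible.
# The number of changes always equals the Fitch step count.

# rooted binary tree traversal orders
.rooted_orders <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  list(ntip = ntip, edge = edge, root = ntip + 1L)
}

# DP + ACCTRAN resolution for a single column of state masks
# masks: integer vector (1,2,3) in tip order; tie_state: root tie-break
.acctran_column <- function(tree, masks, tie_state = NULL) {
  ord <- .rooted_orders(tree)
  edge <- ord$edge
  ntip <- ord$ntip
  nnode <- max(edge)
  INF <- 1e9
  cost <- matrix(0, nnode, 2) # cost of fixing state 0 / 1 at node
  for (i in seq_len(ntip)) {
    cost[i, 1] <- if (bitwAnd(masks[i], 1L) > 0) 0 else INF
    cost[i, 2] <- if (bitwAnd(masks[i], 2L) > 0) 0 else INF
  }
  kids <- vector("list", nnode)
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    kids[[p]] <- c(kids[[p]], edge[r, 2])
  }
  for (r in seq_len(nrow(edge))) { # postorder: children resolved first
    p <- edge[r, 1]
    c_ <- edge[r, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[c_, 1], cost[c_, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[c_, 2], cost[c_, 1] + 1)
  }
  root <- ord$root
  state <- integer(nnode)
  rc <- cost[root, ]
  if (rc[1] < rc[2]) {
    state[root] <- 0L
  } else if (rc[2] < rc[1]) {
    state[root] <- 1L
  } else {
    state[root] <- if (is.null(tie_state)) 0L else tie_state
  }
  # preorder: reverse postorder edge order visits parents first
  changes <- list()
  for (r in rev(seq_len(nrow(edge)))) {
    p <- edge[r, 1]
    c_ <- edge[r, 2]
    f <- state[p]
    v_same <- cost[c_, f + 1]
    v_diff <- cost[c_, 2 - f] + 1
    if (v_diff < v_same) {
      state[c_] <- 1L - f
    } else if (v_same < v_diff) {
      state[c_] <- f
    } else {
      # tie: accelerate (change now) -- except on a pendant edge whose leaf
      # carries the full state set, which never records a change
      state[c_] <- if (c_ <= ntip && masks[c_] == 3L) f else 1L - f
    }
    if (state[c_] != f) {
      changes[[length(changes) + 1]] <- c(node = c_, from = f, to = state[c_])
    }
  }
  list(state = state, changes = changes, length = min(rc))
}

# optimal state of a subtree on its own (used for the root tie-break toward
# the outgroup side): min-cost state, ties to 0
.subtree_pref_state <- function(cost_row) {
  if (cost_row[2] < cost_row[1]) 1L else 0L
}

#' ACCTRAN ancestral states for one character
#'
#' Reconstructs a most-parsimonious assignment of states to every node of a
#' rooted binary tree under accelerated transformation: among equally
#' parsimonious assignments, changes are placed as close to the root as
#' possible. Root ties resolve toward the state supported by the
#' `tie_child` subtree (by default the root's first child, the outgroup
#' side under [root_for_display()]), and to state 0 if that is also
#' ambiguous. The number of reconstructed changes equals the Fitch step
#' count of the column.
#'
#' @param tree a rooted binary `phylo`.
#' @param column per-taxon state symbols or masks (see [fitch_steps()]).
#' @param tie_child which root child (1 or 2) breaks root-state ties.
#' @return list with `states` (0/1 per node, tips first), `changes` (tibble:
#'   `node`, `from`, `to`) and `steps`.
#' @export
acctran_states <- function(tree, column, tie_child = 1L) {
  if (!ape::is.rooted(tree)) abort("ACCTRAN needs a rooted tree")
  if (!ape::is.binary(tree)) abort("ACCTRAN needs a binary tree")
  masks <- .column_masks(column)
  missing_leaf <- setdiff(tree$tip.label, names(masks))
  if (length(missing_leaf) > 0) {
    abort(sprintf("no state for leaf '%s'", missing_leaf[1]))
  }
  masks <- masks[tree$tip.label]
  # root tie-break: preferred state of the chosen root child's subtree
  ord <- .rooted_orders(tree)
  rkids <- ord$edge[ord$edge[, 1] == ord$root, 2]
  tie_state <- .acctran_tie_state(tree, masks, rkids[tie_child])
  res <- .acctran_column(tree, masks, tie_state = tie_state)
  changes <- if (length(res$changes)) {
    as_tibble(do.call(rbind, res$changes))
  } else {
    tibble(node = integer(), from = integer(), to = integer())
  }
  list(states = res$state, changes = changes, steps = res$length)
}

# preferred state of the subtree rooted at `child`
.acctran_tie_state <- function(tree, masks, child) {
  ord <- .rooted_orders(tree)
  edge <- ord$edge
  nnode <- max(edge)
  INF <- 1e9
  cost <- matrix(0, nnode, 2)
  ntip <- ord$ntip
  for (i in seq_len(ntip)) {
    cost[i, 1] <- if (bitwAnd(masks[i], 1L) > 0) 0 else INF
    cost[i, 2] <- if (bitwAnd(masks[i], 2L) > 0) 0 else INF
  }
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    c_ <- edge[r, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[c_, 1], cost[c_, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[c_, 2], cost[c_, 1] + 1)
  }
  .subtree_pref_state(cost[child, ])
}

# ACCTRAN changes for every character at once (vectorised DP): returns a
# tibble with columns node, character, from, to. masks: ntip x nchar grid in
# tip order; tie_child_node breaks root-state ties toward that subtree.
.apomorphy_all <- function(tree, masks, char_idx, tie_child_node) {
  ord <- .rooted_orders(tree)
  edge <- ord$edge
  ntip <- ord$ntip
  nnode <- max(edge)
  nchr <- ncol(masks)
  INF <- 1e9
  c0 <- matrix(0, nnode, nchr)
  c1 <- matrix(0, nnode, nchr)
  tipm <- masks[seq_len(ntip), , drop = FALSE]
  c0[seq_len(ntip), ] <- ifelse(bitwAnd(tipm, 1L) > 0, 0, INF)
  c1[seq_len(ntip), ] <- ifelse(bitwAnd(tipm, 2L) > 0, 0, INF)
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    k <- edge[r, 2]
    c0[p, ] <- c0[p, ] + pmin(c0[k, ], c1[k, ] + 1)
    c1[p, ] <- c1[p, ] + pmin(c1[k, ], c0[k, ] + 1)
  }
  root <- ord$root
  tc <- tie_child_node
  tie <- ifelse(c1[tc, ] < c0[tc, ], 1L, 0L)
  state <- matrix(NA_integer_, nnode, nchr)
  state[root, ] <- ifelse(c0[root, ] < c1[root, ], 0L,
                          ifelse(c1[root, ] < c0[root, ], 1L, tie))
  out_node <- integer()
  out_char <- integer()
  out_from <- integer()
  out_to <- integer()
  for (r in rev(seq_len(nrow(edge)))) { # preorder
    p <- edge[r, 1]
    k <- edge[r, 2]
    f <- state[p, ]
    v_same <- ifelse(f == 0L, c0[k, ], c1[k, ])
    v_diff <- ifelse(f == 0L, c1[k, ], c0[k, ]) + 1
    # full-state leaf: never record a change on its pendant edge
    keep_tie <- if (k <= ntip) masks[k, ] == 3L else rep(FALSE, nchr)
    choose_diff <- v_diff < v_same | (v_diff == v_same & !keep_tie)
    state[k, ] <- ifelse(choose_diff, 1L - f, f)
    hit <- which(state[k, ] != f)
    if (length(hit)) {
      out_node <- c(out_node, rep.int(k, length(hit)))
      out_char <- c(out_char, char_idx[hit])
      out_from <- c(out_from, f[hit])
      out_to <- c(out_to, state[k, hit])
    }
  }
  list(node = out_node, character = out_char, from = out_from, to = out_to)
}

# descendant tip labels of every node
.node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- max(edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    below[[p]] <- c(below[[p]], below[[edge[r, 2]]])
  }
  lapply(below, sort)
}

#' Per-branch apomorphy list under ACCTRAN
#'
#' Maps every reconstructed character-state transformation onto the branch
#' it occurs on, with branches identified by the set of taxa descending
#' from them (their child bipartition on the display rooting).
#'
#' @param tree a `phylo`; if unrooted it is rooted with
#'   [root_for_display()] on `outgroup`.
#' @param m a [char_matrix].
#' @param outgroup outgroup labels used to root unrooted input and to break
#'   root-state ties toward the outgroup side.
#' @return tibble of class `apomorphy_map` subset: columns `branch` (display
#'   label of the descendant taxon set), `clade` (list column), `character`,
#'   `from`, `to`.
#' @examples
#' res <- branch_and_bound(coronal_matrix())
#' apo <- apomorphy_list(res$trees[[1]], coronal_matrix(),
#'                       outgroup = coronal_outgroups())
#' @export
apomorphy_list <- function(tree, m, outgroup = NULL) {
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      abort("tree is unrooted: supply `outgroup` to root for display")
    }
    tree <- root_for_display(tree, outgroup)
  }
  masks <- state_masks(m)
  idx <- match(tree$tip.label, rownames(masks))
  if (anyNA(idx)) {
    abort(sprintf("no matrix row for leaf '%s'",
                  tree$tip.label[which(is.na(idx))[1]]))
  }
  masks <- masks[idx, , drop = FALSE]
  char_idx <- m$characters$index[m$characters$active]
  clades <- .node_clades(tree)
  ord <- .rooted_orders(tree)
  rkids <- ord$edge[ord$edge[, 1] == ord$root, 2]
  tie_child_node <- if (!is.null(outgroup)) {
    og <- intersect(outgroup, tree$tip.label)
    side <- vapply(rkids, function(k) all(og %in% clades[[k]]), logical(1))
    if (any(side)) rkids[which(side)[1]] else rkids[1]
  } else {
    rkids[1]
  }
  ch <- .apomorphy_all(tree, masks, char_idx, tie_child_node)
  if (length(ch$node) == 0) {
    return(tibble(branch = character(), clade = list(),
                  character = integer(), from = integer(), to = integer()))
  }
  tibble(
    branch = vapply(clades[ch$node], .split_label, character(1)),
    clade = clades[ch$node],
    character = ch$character,
    from = ch$from,
    to = ch$to
  )
}

# transformation keys of one tree without tibble overhead (the inner loop of
# unambiguous_changes over large optimal sets)
.apomorphy_keys <- function(tree, masks_all, char_idx, outgroup) {
  if (!ape::is.rooted(tree)) {
    tree <- suppressWarnings(root_for_display(tree, outgroup))
  }
  masks <- masks_all[match(tree$tip.label, rownames(masks_all)), ,
                     drop = FALSE]
  clades <- .node_clades(tree)
  ord <- .rooted_orders(tree)
  rkids <- ord$edge[ord$edge[, 1] == ord$root, 2]
  og <- intersect(outgroup %||% character(), tree$tip.label)
  side <- vapply(rkids, function(k) length(og) > 0 && all(og %in% clades[[k]]),
                 logical(1))
  tie_child_node <- if (any(side)) rkids[which(side)[1]] else rkids[1]
  ch <- .apomorphy_all(tree, masks, char_idx, tie_child_node)
  if (length(ch$node) == 0) return(character())
  paste(vapply(clades[ch$node], .split_key, character(1)),
        ch$character, ch$from, ch$to, sep = "\x1e")
}

#' Transformations shared by every optimal tree
#'
#' Intersects the ACCTRAN apomorphy lists of a set of (typically all
#' most-parsimonious) trees: a transformation is retained only if the same
#' character changes the same way on the branch defined by the same child
#' bipartition in every tree. Branches absent from any tree are dropped.
#'
#' @param trees a `multiPhylo` (or list) of trees over the matrix taxa.
#' @inheritParams apomorphy_list
#' @return tibble like [apomorphy_list()] with an additional
#'   `unambiguous` column (all `TRUE`).
#' @export
unambiguous_changes <- function(trees, m, outgroup = NULL) {
  trees <- .as_tree_list(trees)
  if (length(trees) == 0) abort("empty tree set")
  key_of <- function(ap) {
    paste(vapply(ap$clade, .split_key, character(1)),
          ap$character, ap$from, ap$to, sep = "\x1e")
  }
  # per-tree fallback rootings are routine over large tree sets (warnings
  # suppressed); only the first tree needs the full table, the rest only
  # contribute their transformation keys
  first <- suppressWarnings(apomorphy_list(trees[[1]], m,
                                           outgroup = outgroup))
  first$key <- key_of(first)
  shared <- first$key
  masks_all <- state_masks(m)
  char_idx <- m$characters$index[m$characters$active]
  for (i in seq_along(trees)[-1]) {
    if (length(shared) == 0) break
    shared <- intersect(shared, .apomorphy_keys(trees[[i]], masks_all,
                                                char_idx, outgroup))
  }
  out <- first[first$key %in% shared, , drop = FALSE]
  out$key <- NULL
  out$unambiguous <- TRUE
  out[order(out$character), ]
}
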