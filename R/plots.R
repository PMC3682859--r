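# ggplot2 displays: state-grid view of a character matrix, cladogram view
# of a consensus tree, and a support bar chart.

#' Plot a character matrix as a state grid
#'
#' @param object a [char_matrix].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.char_matrix <- function(object, ...) {
  d <- as_tibble(object)
  d$taxon <- factor(d$taxon, levels = rev(taxa_labels(object)))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$character),
                                  y = .data$taxon,
                                  fill = .data$symbol)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(
      "0" = "grey95", "1" = "grey25", "?" = "#9ecae1",
      "-" = "white", "0/1" = "#fdae6b")) +
    ggplot2::labs(x = "character", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

# simple rectangular cladogram layout for a rooted(ish) phylo
.tree_layout <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- max(edge)
  ypos <- rep(NA_real_, nnode)
  ypos[seq_len(ntip)] <- seq_len(ntip)
  depth <- rep(0, nnode)
  kids <- vector("list", nnode)
  for (r in seq_len(nrow(edge))) {
    kids[[edge[r, 1]]] <- c(kids[[edge[r, 1]]], edge[r, 2])
  }
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]
    if (is.na(ypos[p])) {
      ys <- ypos[kids[[p]]]
      if (!anyNA(ys)) ypos[p] <- mean(range(ys))
    }
  }
  root <- ntip + 1L
  depth[root] <- 0
  for (r in rev(seq_len(nrow(edge)))) {
    depth[edge[r, 2]] <- depth[edge[r, 1]] + 1
  }
  maxd <- max(depth)
  x <- ifelse(seq_len(nnode) <= ntip, maxd, depth)
  list(x = x, y = ypos, edge = edge, ntip = ntip)
}

#' Plot a consensus tree as a cladogram
#'
#' Internal edges are labelled with the consensus frequency (and jackknife
#' support when present, as `frequency/jackknife`).
#'
#' @param object a `consensus_tree`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.consensus_tree <- function(object, ...) {
  tree <- object$tree
  lay <- .tree_layout(tree)
  edge <- lay$edge
  seg <- tibble(
    x = lay$x[edge[, 1]], xend = lay$x[edge[, 2]],
    y = lay$y[edge[, 1]], yend = lay$y[edge[, 2]]
  )
  tips <- tibble(x = lay$x[seq_len(lay$ntip)], y = lay$y[seq_len(lay$ntip)],
                 label = tree$tip.label)
  nl <- tree$node.label %||% rep("", max(edge) - lay$ntip)
  nodes <- tibble(
    x = lay$x[lay$ntip + seq_along(nl)],
    y = lay$y[lay$ntip + seq_along(nl)],
    label = nl
  )
  nodes <- nodes[nzchar(nodes$label), , drop = FALSE]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x, yend = .data$yend)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$yend,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 0, nudge_x = 0.05, size = 3,
                       fontface = "italic") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 1.1, vjust = -0.4, size = 2.8) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.35))) +
    ggplot2::theme_void()
}

#' Plot jackknife support values
#'
#' @param object a `jackknife_support`.
#' @param min_support only show bipartitions at or above this support.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.jackknife_support <- function(object, min_support = 0, ...) {
  d <- object$support
  d <- d[d$support >= min_support, , drop = FALSE]
  d$bipartition <- factor(d$bipartition, levels = rev(d$bipartition))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$support, y = .data$bipartition)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = 50, linetype = 2) +
    ggplot2::labs(x = "jackknife support (%)", y = NULL) +
    ggplot2::theme_minimal()
}
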