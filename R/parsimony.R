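# Fitch (unordered) parsimony scoring of binary characters with full-state
# cells, per-character step bounds, ensemble fit indices and character
# classification.

# normalise a per-taxon column (symbols or masks) to an integer mask vector
.column_masks <- function(column) {
  if (is.character(column)) {
    setNames(.sym_to_mask(column), names(column))
  } else {
    stopifnot(all(column %in% 1:3))
    column
  }
}

#' Fitch step count of one character on a tree
#'
#' Computes the minimum number of binary state changes needed to explain a
#' single character column on a tree, allowing missing/inapplicable/
#' polymorphic leaves to take whichever state is cheapest.
#'
#' @param tree a `phylo`; rooted or unrooted (the count is the same).
#' @param column named vector over the tree's leaves: symbols (`"0"`, `"1"`,
#'   `"?"`, `"-"`, `"0/1"`) or state-set masks (1, 2, 3).
#' @return integer number of steps.
#' @examples
#' tr <- read_newick(text = "((A,B),(C,D));")
#' fitch_steps(tr, c(A = "0", B = "0", C = "1", D = "1"))
#' @export
fitch_steps <- function(tree, column) {
  masks <- .column_masks(column)
  missing_leaf <- setdiff(tree$tip.label, names(masks))
  if (length(missing_leaf) > 0) {
    abort(sprintf("no state for leaf '%s'", missing_leaf[1]))
  }
  st <- matrix(masks[tree$tip.label], ncol = 1)
  as.integer(fitch_counts_cpp(tree$edge, length(tree$tip.label), st))
}

#' Parsimony length of a tree on a character matrix
#'
#' Sums Fitch step counts over the active characters of a matrix.
#'
#' @param tree a `phylo` whose leaves are the matrix taxa.
#' @param m a [char_matrix].
#' @return an object of class `parsimony_score`: list with `total_length`
#'   and the integer vector `per_character_steps` (named by character index).
#' @export
tree_length <- function(tree, m) {
  masks <- state_masks(m)
  idx <- match(tree$tip.label, rownames(masks))
  if (anyNA(idx)) {
    abort(sprintf("no matrix row for leaf '%s'",
                  tree$tip.label[which(is.na(idx))[1]]))
  }
  steps <- fitch_counts_cpp(tree$edge, length(tree$tip.label),
                            masks[idx, , drop = FALSE])
  structure(
    list(total_length = sum(steps),
         per_character_steps = setNames(as.integer(steps),
                                        m$characters$index[m$characters$active])),
    class = "parsimony_score"
  )
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("<parsimony_score> total length %d over %d characters\n",
              x$total_length, length(x$per_character_steps)))
  invisible(x)
}

# unambiguous (singleton) state tallies of each column of a mask matrix
.state_tallies <- function(masks) {
  n0 <- colSums(masks == 1L)
  n1 <- colSums(masks == 2L)
  cbind(n0 = n0, n1 = n1)
}

#' Per-character step bounds
#'
#' `min_steps()` is the smallest number of changes any tree can require:
#' one less than the number of states unambiguously observed (0 or 1 for a
#' binary character). `max_steps()` is the largest number any tree can
#' require, which for a binary character equals the count of unambiguous
#' cells carrying the minority state; full-state cells (missing,
#' inapplicable, polymorphic) never contribute.
#'
#' @param column per-taxon state symbols or masks (see [fitch_steps()]).
#' @return integer.
#' @export
min_steps <- function(column) {
  masks <- .column_masks(column)
  as.integer((any(masks == 1L)) + (any(masks == 2L)) > 1)
}

#' @rdname min_steps
#' @export
max_steps <- function(column) {
  masks <- .column_masks(column)
  n0 <- sum(masks == 1L)
  n1 <- sum(masks == 2L)
  if (n0 == 0L || n1 == 0L) return(0L)
  as.integer(min(n0, n1))
}

.min_steps_all <- function(masks) {
  t <- .state_tallies(masks)
  as.integer((t[, "n0"] > 0) + (t[, "n1"] > 0) > 1)
}

.max_steps_all <- function(masks) {
  t <- .state_tallies(masks)
  out <- pmin(t[, "n0"], t[, "n1"])
  out[t[, "n0"] == 0 | t[, "n1"] == 0] <- 0L
  as.integer(out)
}

#' Ensemble fit statistics (CI, RI, RC)
#'
#' Computes the ensemble consistency index (minimum conceivable total steps
#' over observed steps), retention index and rescaled consistency index for
#' a tree length obtained on a matrix. All active characters are included,
#' informative or not; `ci_informative` additionally reports the
#' alternative convention that drops parsimony-uninformative characters.
#'
#' @param m a [char_matrix].
#' @param score a `parsimony_score` from [tree_length()], or an integer
#'   observed total length.
#' @return object of class `fit_statistics`: list with `ci`, `ri`, `rc`,
#'   `min_total`, `max_total`, `observed_total`, `ci_informative` and a
#'   `degenerate` flag (observed length zero).
#' @export
ensemble_indices <- function(m, score) {
  obs <- if (inherits(score, "parsimony_score")) score$total_length
         else as.integer(score)
  masks <- state_masks(m)
  mins <- .min_steps_all(masks)
  maxs <- .max_steps_all(masks)
  min_total <- sum(mins)
  max_total <- sum(maxs)
  degenerate <- obs == 0
  if (degenerate) {
    warn("observed length is zero; consistency index reported as 1")
    ci <- 1
  } else {
    ci <- min_total / obs
  }
  ri <- if (max_total > min_total) (max_total - obs) / (max_total - min_total)
        else NA_real_
  rc <- if (is.na(ri)) NA_real_ else ci * ri
  info <- .classify_all(masks)$status == "informative"
  obs_i <- if (inherits(score, "parsimony_score")) {
    sum(score$per_character_steps[info])
  } else {
    NA_integer_
  }
  ci_informative <- if (!is.na(obs_i) && obs_i > 0) sum(mins[info]) / obs_i
                    else NA_real_
  structure(
    list(ci = ci, ri = ri, rc = rc, min_total = min_total,
         max_total = max_total, observed_total = obs,
         ci_informative = ci_informative, degenerate = degenerate),
    class = "fit_statistics"
  )
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf(
    "<fit_statistics> length %d (min %d, max %d): CI %.2f, RI %.2f, RC %.2f\n",
    x$observed_total, x$min_total, x$max_total, x$ci, x$ri, x$rc))
  if (!is.na(x$ci_informative)) {
    cat(sprintf("  CI over informative characters only: %.2f\n",
                x$ci_informative))
  }
  invisible(x)
}

.classify_all <- function(masks) {
  t <- .state_tallies(masks)
  n0 <- t[, "n0"]
  n1 <- t[, "n1"]
  status <- rep("constant", length(n0))
  status[n0 > 0 & n1 > 0] <- "autapomorphic"
  status[n0 >= 2 & n1 >= 2] <- "informative"
  # autapomorphic requires exactly one cell in the minority state
  aut <- status == "autapomorphic" & pmin(n0, n1) != 1L
  status[aut] <- "constant"
  taxon <- rep(NA_character_, length(n0))
  for (j in which(status == "autapomorphic")) {
    minority <- if (n0[j] < n1[j]) 1L else 2L
    taxon[j] <- rownames(masks)[which(masks[, j] == minority)]
  }
  list(status = status, autapomorphic_taxon = taxon)
}

#' Classify characters as constant, autapomorphic or informative
#'
#' A character is parsimony-informative when at least two states are each
#' carried unambiguously by two or more taxa; autapomorphic when it varies
#' but exactly one unambiguous cell carries the minority state; constant
#' otherwise. Missing, inapplicable and polymorphic cells never count
#' towards the tallies.
#'
#' @param m a [char_matrix].
#' @return tibble with columns `character`, `definition`, `status`,
#'   `autapomorphic_taxon`.
#' @examples
#' classify_characters(coronal_matrix())
#' @export
classify_characters <- function(m) {
  masks <- state_masks(m)
  cls <- .classify_all(masks)
  tibble(
    character = m$characters$index[m$characters$active],
    definition = m$characters$definition[m$characters$active],
    status = cls$status,
    autapomorphic_taxon = cls$autapomorphic_taxon
  )
}

#' Per-character parsimony report
#'
#' Tabulates, for each active character, the observed steps on a given tree
#' together with its step bounds, per-character consistency and retention
#' indices, and classification.
#'
#' @param m a [char_matrix].
#' @param tree a `phylo` (typically one of the most-parsimonious trees).
#' @return tibble with one row per character.
#' @export
character_report <- function(m, tree) {
  sc <- tree_length(tree, m)
  masks <- state_masks(m)
  mins <- .min_steps_all(masks)
  maxs <- .max_steps_all(masks)
  steps <- as.integer(sc$per_character_steps)
  cls <- .classify_all(masks)
  tibble(
    character = m$characters$index[m$characters$active],
    steps = steps,
    min_steps = mins,
    max_steps = maxs,
    ci = ifelse(steps > 0, mins / steps, NA_real_),
    ri = ifelse(maxs > mins, (maxs - steps) / (maxs - mins), NA_real_),
    status = cls$status
  )
}
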