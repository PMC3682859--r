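# The character-matrix container used throughout: a taxa x characters grid of
# binary state sets. Each cell is a 2-bit mask (1 = {0}, 2 = {1}, 3 = {0,1})
# plus a source tag recording how the cell was written in the data source:
# "resolved", "missing" ("?"), "inapplicable" ("-") or "ambiguous" ("0/1").
# Missing, inapplicable and ambiguous cells all score as the full state set
# {0,1}; the tag exists for round-trip fidelity only.

.TAGS <- c("resolved", "missing", "inapplicable", "ambiguous")

.sym_to_mask <- function(sym) {
  out <- integer(length(sym))
  out[sym == "0"] <- 1L
  out[sym == "1"] <- 2L
  out[sym %in% c("?", "-", "0/1", "1/0", "(01)", "(10)", "{01}", "{10}")] <- 3L
  bad <- out == 0L
  if (any(bad)) {
    abort(sprintf("unrecognised state symbol(s): %s",
                  paste(unique(sym[bad]), collapse = ", ")))
  }
  out
}

.sym_to_tag <- function(sym) {
  out <- rep("resolved", length(sym))
  out[sym == "?"] <- "missing"
  out[sym == "-"] <- "inapplicable"
  out[sym %in% c("0/1", "1/0", "(01)", "(10)", "{01}", "{10}")] <- "ambiguous"
  out
}

.cell_symbol <- function(mask, tag, polymorphic_style = "0/1") {
  sym <- character(length(mask))
  sym[mask == 1L] <- "0"
  sym[mask == 2L] <- "1"
  full <- mask == 3L
  sym[full & tag == "missing"] <- "?"
  sym[full & tag == "inapplicable"] <- "-"
  sym[full & tag == "ambiguous"] <- polymorphic_style
  sym
}

new_char_matrix <- function(cells, tags, taxa, characters) {
  stopifnot(is.matrix(cells), is.matrix(tags))
  dimnames(cells) <- list(taxa, NULL)
  dimnames(tags) <- list(taxa, NULL)
  structure(
    list(taxa = taxa, characters = characters, cells = cells, tags = tags),
    class = "char_matrix"
  )
}

.validate_char_matrix <- function(m) {
  if (length(m$taxa) != nrow(m$cells)) {
    abort("taxon list and cell grid disagree in size")
  }
  if (nrow(m$characters) != ncol(m$cells)) {
    abort("character list and cell grid disagree in size")
  }
  if (anyDuplicated(m$taxa)) {
    abort(sprintf("duplicate taxon label: %s",
                  m$taxa[duplicated(m$taxa)][1]))
  }
  if (anyDuplicated(m$characters$index)) abort("duplicate character index")
  if (!all(m$cells %in% 1:3)) abort("cell state mask outside {1,2,3}")
  if (!all(m$tags %in% .TAGS)) abort("unknown cell source tag")
  if (any(m$cells == 3L & m$tags == "resolved") ||
      any(m$cells != 3L & m$tags != "resolved")) {
    abort("cell source tags inconsistent with state sets")
  }
  invisible(m)
}

#' Build a binary character matrix
#'
#' Constructs the character-matrix object used by all analysis functions from
#' a grid of printed state symbols. Allowed symbols are `"0"`, `"1"`,
#' `"?"` (missing), `"-"` (inapplicable) and `"0/1"` (polymorphic/uncertain).
#' Missing, inapplicable and polymorphic cells are all scored as the full
#' state set \{0,1\} during optimisation; the distinction between them is
#' retained as a per-cell source tag so that files round-trip faithfully.
#'
#' @param x character (or 0/1 numeric) matrix of state symbols, with taxa as
#'   rows. Row names are used as taxon labels unless `taxa` is given.
#' @param taxa character vector of taxon labels.
#' @param definitions optional character vector of per-character definition
#'   strings (recycled into the character table).
#' @return An object of class `char_matrix`: a list with elements `taxa`,
#'   `characters` (a tibble with columns `index`, `definition`, `active`),
#'   `cells` (state-set masks) and `tags` (cell source tags).
#' @examples
#' m <- char_matrix(rbind(A = c("0", "1"), B = c("1", "?"), C = c("1", "1")))
#' n_taxa(m)
#' @export
char_matrix <- function(x, taxa = rownames(x), definitions = NULL) {
  if (is.numeric(x)) {
    x <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dimnames(x))
  }
  if (is.null(taxa)) abort("taxon labels required (row names or `taxa`)")
  if (ncol(x) < 1) abort("matrix must contain at least one character")
  sym <- as.vector(x)
  cells <- matrix(.sym_to_mask(sym), nrow(x), ncol(x))
  tags <- matrix(.sym_to_tag(sym), nrow(x), ncol(x))
  characters <- tibble(
    index = seq_len(ncol(x)),
    definition = if (is.null(definitions)) {
      sprintf("character %d", seq_len(ncol(x)))
    } else {
      rep_len(definitions, ncol(x))
    },
    active = TRUE
  )
  m <- new_char_matrix(cells, tags, as.character(taxa), characters)
  .validate_char_matrix(m)
  m
}

#' @export
print.char_matrix <- function(x, n = 6, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d binary characters\n",
              n_taxa(x), n_characters(x)))
  tag_n <- table(factor(x$tags, levels = .TAGS))
  cat(sprintf("  cells: %d resolved, %d missing, %d inapplicable, %d ambiguous\n",
              tag_n[["resolved"]], tag_n[["missing"]],
              tag_n[["inapplicable"]], tag_n[["ambiguous"]]))
  shown <- utils::head(seq_len(n_taxa(x)), n)
  for (i in shown) {
    cat(sprintf("  %-28s %s\n", x$taxa[i],
                paste(.cell_symbol(x$cells[i, ], x$tags[i, ]), collapse = " ")))
  }
  if (n_taxa(x) > length(shown)) {
    cat(sprintf("  ... %d more taxa\n", n_taxa(x) - length(shown)))
  }
  invisible(x)
}

#' Matrix dimensions and labels
#'
#' @param m a `char_matrix`.
#' @return `n_taxa()` and `n_characters()` return integers; `taxa_labels()`
#'   the taxon labels.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(m) nrow(m$characters)

#' @rdname n_taxa
#' @export
taxa_labels <- function(m) m$taxa

#' State-set masks of a character matrix
#'
#' Returns the taxa x characters grid of 2-bit state-set masks
#' (1 = state 0 only, 2 = state 1 only, 3 = either state) used by the
#' scoring engines.
#'
#' @param m a `char_matrix`.
#' @param active_only drop characters whose `active` flag is `FALSE`?
#' @return integer matrix with taxa as row names.
#' @export
state_masks <- function(m, active_only = TRUE) {
  keep <- if (active_only) m$characters$active else rep(TRUE, n_characters(m))
  out <- m$cells[, keep, drop = FALSE]
  rownames(out) <- m$taxa
  out
}

#' @export
as_tibble.char_matrix <- function(x, ...) {
  tibble(
    taxon = rep(x$taxa, times = n_characters(x)),
    character = rep(x$characters$index, each = n_taxa(x)),
    symbol = .cell_symbol(as.vector(x$cells), as.vector(x$tags)),
    tag = as.vector(x$tags)
  )
}

#' Remove taxa from a character matrix
#'
#' Drops the given taxon rows; the character set is unchanged. At least two
#' taxa must remain.
#'
#' @param m a `char_matrix`.
#' @param labels taxon labels to remove (may be empty).
#' @return the pruned `char_matrix`.
#' @export
prune_taxa <- function(m, labels) {
  if (length(labels) == 0) return(m)
  unknown <- setdiff(labels, m$taxa)
  if (length(unknown) > 0) {
    abort(sprintf("unknown taxon label(s): %s", paste(unknown, collapse = ", ")))
  }
  keep <- !(m$taxa %in% labels)
  if (sum(keep) < 2) abort("pruning would leave fewer than 2 taxa")
  out <- new_char_matrix(m$cells[keep, , drop = FALSE],
                         m$tags[keep, , drop = FALSE],
                         m$taxa[keep], m$characters)
  .validate_char_matrix(out)
  out
}

#' @method all.equal char_matrix
#' @export
all.equal.char_matrix <- function(target, current, ...) {
  if (!inherits(current, "char_matrix")) return("not a char_matrix")
  msgs <- character()
  if (!identical(target$taxa, current$taxa)) msgs <- c(msgs, "taxa differ")
  if (!identical(unname(target$cells), unname(current$cells))) {
    msgs <- c(msgs, "cell state sets differ")
  }
  if (!identical(unname(target$tags), unname(current$tags))) {
    msgs <- c(msgs, "cell source tags differ")
  }
  if (!identical(target$characters$definition, current$characters$definition)) {
    msgs <- c(msgs, "character definitions differ")
  }
  if (length(msgs) == 0) TRUE else msgs
}
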