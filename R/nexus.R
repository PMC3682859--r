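# NEXUS reader/writer for binary character matrices. Hand-written rather than
# delegated so that the missing ("?") / inapplicable ("-") / polymorphic
# ("(01)") cell distinction survives a round trip; all three score as the
# full state set downstream.

.nexus_quote <- function(x) {
  paste0("'", gsub("'", "''", x), "'")
}

.nexus_strip_comments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

# split on a delimiter while respecting single-quoted strings
.nexus_split <- function(txt, delim) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  out <- character()
  buf <- character()
  inq <- FALSE
  for (ch in chars) {
    if (ch == "'") inq <- !inq
    if (ch == delim && !inq) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  if (length(buf) && nzchar(trimws(paste(buf, collapse = "")))) {
    out <- c(out, paste(buf, collapse = ""))
  }
  trimws(out)
}

.nexus_statements <- function(txt) .nexus_split(txt, ";")

# read one (possibly quoted) token off the head of a string; returns the
# token and the remainder
.nexus_token <- function(s) {
  s <- sub("^\\s+", "", s)
  if (s == "") return(NULL)
  if (substr(s, 1, 1) == "'") {
    m <- regexpr("^'(?:[^']|'')*'", s)
    if (m == -1) abort("unterminated quoted label in NEXUS input")
    tok <- regmatches(s, m)
    rest <- substr(s, attr(m, "match.length") + 1, nchar(s))
    tok <- gsub("''", "'", substr(tok, 2, nchar(tok) - 1))
    list(token = tok, rest = rest)
  } else {
    m <- regexpr("^\\S+", s)
    tok <- regmatches(s, m)
    rest <- substr(s, attr(m, "match.length") + 1, nchar(s))
    list(token = gsub("_", " ", tok), rest = rest)
  }
}

.parse_state_string <- function(s, taxon, missing_sym = "?", gap_sym = "-") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character()
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1
    } else if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1
      grp <- character()
      while (j <= n && chars[j] != close) {
        if (!grepl("^[\\s/,]$", chars[j], perl = TRUE)) grp <- c(grp, chars[j])
        j <- j + 1
      }
      if (j > n) {
        abort(sprintf("taxon '%s': unterminated state group at position %d",
                      taxon, i))
      }
      grp <- sort(unique(grp))
      if (!identical(grp, c("0", "1"))) {
        abort(sprintf("taxon '%s': state group '%s' is not a subset of {0,1}",
                      taxon, paste(grp, collapse = "")))
      }
      out <- c(out, "0/1")
      i <- j + 1
    } else if (ch == missing_sym) {
      out <- c(out, "?")
      i <- i + 1
    } else if (ch == gap_sym) {
      out <- c(out, "-")
      i <- i + 1
    } else if (ch %in% c("0", "1")) {
      out <- c(out, ch)
      i <- i + 1
    } else {
      abort(sprintf(
        "taxon '%s': undeclared state symbol '%s' at position %d",
        taxon, ch, i))
    }
  }
  out
}

#' Read a binary character matrix from a NEXUS document
#'
#' Parses the TAXA and CHARACTERS (or DATA) blocks of a NEXUS file with
#' binary standard-format data. Cells written `?` map to missing, `-` to
#' inapplicable and `(01)`/`{01}` to polymorphic; all three are scored as the
#' full state set \{0,1\} by the analysis functions. CHARSTATELABELS, when
#' present, populate the character definition strings.
#'
#' @param file path to a NEXUS file, or `NULL` when `text` is given.
#' @param text a NEXUS document as a single string (overrides `file`).
#' @return a [char_matrix].
#' @seealso [write_nexus()]
#' @export
read_nexus <- function(file = NULL, text = NULL) {
  txt <- if (!is.null(text)) text else paste(readLines(file), collapse = "\n")
  txt <- .nexus_strip_comments(txt)
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    abort("not a NEXUS document (missing #NEXUS header)")
  }
  mblocks <- gregexpr("(?is)\\bBEGIN\\s+(\\w+)\\s*;(.*?)\\bEND\\s*;", txt,
                      perl = TRUE)
  blocks <- regmatches(txt, mblocks)[[1]]
  if (length(blocks) == 0) abort("no NEXUS blocks found")
  names(blocks) <- toupper(sub("(?is)^\\s*BEGIN\\s+(\\w+).*", "\\1", blocks,
                               perl = TRUE))
  cb <- blocks[names(blocks) %in% c("CHARACTERS", "DATA")]
  if (length(cb) == 0) abort("no CHARACTERS or DATA block found")
  body <- sub("(?is)^\\s*BEGIN\\s+\\w+\\s*;", "", cb[[1]], perl = TRUE)
  body <- sub("(?is)\\bEND\\s*;\\s*$", "", body, perl = TRUE)
  stmts <- .nexus_statements(body)
  cmd <- toupper(sub("^\\s*(\\S+).*$", "\\1", stmts))

  nchar_decl <- NA_integer_
  missing_sym <- "?"
  gap_sym <- "-"
  defs <- NULL

  dim_stmt <- stmts[cmd == "DIMENSIONS"]
  if (length(dim_stmt)) {
    m <- regexpr("(?i)NCHAR\\s*=\\s*(\\d+)", dim_stmt[1], perl = TRUE)
    if (m != -1) {
      nchar_decl <- as.integer(sub("(?i).*NCHAR\\s*=\\s*(\\d+).*", "\\1",
                                   dim_stmt[1], perl = TRUE))
    }
  }
  if (!is.na(nchar_decl) && nchar_decl < 1) {
    abort("NEXUS document declares zero characters")
  }

  fmt_stmt <- stmts[cmd == "FORMAT"]
  if (length(fmt_stmt)) {
    f <- fmt_stmt[1]
    g <- function(key) {
      m <- regexpr(paste0("(?i)", key, "\\s*=\\s*(\\S)"), f, perl = TRUE)
      if (m == -1) return(NULL)
      sub(paste0("(?i).*", key, "\\s*=\\s*(\\S).*"), "\\1", f, perl = TRUE)
    }
    missing_sym <- g("MISSING") %||% "?"
    gap_sym <- g("GAP") %||% "-"
    m <- regexpr("(?i)SYMBOLS\\s*=\\s*\"([^\"]*)\"", f, perl = TRUE)
    if (m != -1) {
      syms <- sub("(?i).*SYMBOLS\\s*=\\s*\"([^\"]*)\".*", "\\1", f, perl = TRUE)
      syms <- setdiff(strsplit(syms, "")[[1]], " ")
      if (!all(syms %in% c("0", "1"))) {
        abort(sprintf("only binary symbols are supported; declared \"%s\"",
                      paste(syms, collapse = "")))
      }
    }
  }

  csl_stmt <- stmts[cmd == "CHARSTATELABELS"]
  if (length(csl_stmt)) {
    s <- sub("(?is)^\\s*CHARSTATELABELS\\s*", "", csl_stmt[1], perl = TRUE)
    entries <- .nexus_split(s, ",")
    defs_idx <- integer()
    defs_txt <- character()
    for (e in entries) {
      e <- trimws(e)
      if (e == "") next
      tk <- .nexus_token(e)
      idx <- suppressWarnings(as.integer(tk$token))
      lab <- .nexus_token(tk$rest)
      if (!is.na(idx) && !is.null(lab)) {
        defs_idx <- c(defs_idx, idx)
        defs_txt <- c(defs_txt, lab$token)
      }
    }
    if (length(defs_idx)) {
      defs <- rep(NA_character_, max(defs_idx))
      defs[defs_idx] <- defs_txt
    }
  }

  mat_i <- which(cmd == "MATRIX")
  if (length(mat_i) == 0) abort("no MATRIX command in CHARACTERS block")
  mat_txt <- sub("(?is)^\\s*MATRIX", "", stmts[mat_i[1]], perl = TRUE)
  rows <- strsplit(mat_txt, "\n")[[1]]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0) abort("empty MATRIX in CHARACTERS block")

  taxa <- character()
  states <- list()
  for (r in rows) {
    tk <- .nexus_token(r)
    if (is.null(tk)) next
    st <- .parse_state_string(tk$rest, tk$token, missing_sym, gap_sym)
    taxa <- c(taxa, tk$token)
    states[[length(states) + 1]] <- st
  }
  lens <- lengths(states)
  nch <- if (!is.na(nchar_decl)) nchar_decl else max(lens)
  if (nch < 1) abort("NEXUS document declares zero characters")
  bad <- which(lens != nch)
  if (length(bad)) {
    abort(sprintf("ragged matrix row for taxon '%s': %d states, expected %d",
                  taxa[bad[1]], lens[bad[1]], nch))
  }
  x <- do.call(rbind, states)
  rownames(x) <- taxa
  if (!is.null(defs)) defs <- rep_len(ifelse(is.na(defs), "", defs), nch)
  char_matrix(x, definitions = defs)
}

#' Write a binary character matrix as a NEXUS document
#'
#' Emits TAXA and CHARACTERS blocks with `FORMAT SYMBOLS="01" MISSING=?
#' GAP=-`; polymorphic cells are written `(01)`, missing cells `?` and
#' inapplicable cells `-`, so [read_nexus()] recovers the matrix exactly,
#' source tags included.
#'
#' @param m a [char_matrix].
#' @param file optional path; when `NULL` the document is returned as a
#'   character string.
#' @return the NEXUS document, invisibly when written to `file`.
#' @export
write_nexus <- function(m, file = NULL) {
  .validate_char_matrix(m)
  nt <- n_taxa(m)
  nc <- n_characters(m)
  lab <- vapply(m$taxa, .nexus_quote, character(1))
  width <- max(nchar(lab))
  rows <- vapply(seq_len(nt), function(i) {
    sym <- .cell_symbol(m$cells[i, ], m$tags[i, ], polymorphic_style = "(01)")
    sprintf("    %-*s  %s", width, lab[i], paste(sym, collapse = ""))
  }, character(1))
  csl <- paste(sprintf("    %d %s", m$characters$index,
                       vapply(m$characters$definition, .nexus_quote,
                              character(1))),
               collapse = ",\n")
  doc <- paste0(
    "#NEXUS\n\n",
    "BEGIN TAXA;\n",
    sprintf("  DIMENSIONS NTAX=%d;\n", nt),
    "  TAXLABELS\n",
    paste0("    ", lab, collapse = "\n"), "\n  ;\nEND;\n\n",
    "BEGIN CHARACTERS;\n",
    sprintf("  DIMENSIONS NCHAR=%d;\n", nc),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;\n",
    "  CHARSTATELABELS\n", csl, "\n  ;\n",
    "  MATRIX\n",
    paste(rows, collapse = "\n"),
    "\n  ;\nEND;\n"
  )
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
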