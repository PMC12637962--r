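# BioC-style document model.
#
# A collection is an ordered list of documents; a document is an ordered list
# of passages; table structure is carried by cell annotations so that the
# passage text stays minable as plain text while the grid remains losslessly
# recoverable. Conventions (documented, since BioC deployments differ):
#   * offsets are 0-based CHARACTER offsets, half-open spans;
#   * annotation spans are relative to their passage's text;
#   * a table passage's text is the row-major linearization of the grid with
#     TAB between cells and NEWLINE between rows;
#   * captions are separate `table_caption` passages immediately preceding
#     their table, linked via the `caption_for` infon;
#   * document text is the concatenation of passage texts separated by a
#     single newline, which fixes every passage offset.

PASSAGE_TYPES <- c("title", "paragraph", "table", "table_caption")
MEDIA_CLASSES <- c("delimited_text", "plain_text", "spreadsheet",
                   "word_processor", "slides", "pdf", "archive", "non_textual")

# reserved infon keys round-tripped into structured fields, not user infons
RESERVED_PASSAGE_INFONS <- c("type", "table_id", "n_rows", "n_cols",
                             "source_sheet")
RESERVED_DOC_INFONS <- c("media_class")

canonical_infons <- function(infons) {
  if (is.null(infons) || length(infons) == 0L)
    return(structure(character(0), names = character(0)))
  infons <- vapply(infons, as.character, "")
  if (is.null(names(infons)) || anyNA(names(infons)) || any(names(infons) == ""))
    stop("infons must be a named character vector")
  if (anyDuplicated(names(infons))) stop("duplicate infon keys")
  infons[order(names(infons), method = "radix")]
}

new_cell_annotations <- function(row, col, start, end) {
  data.frame(row = as.integer(row), col = as.integer(col),
             start = as.integer(start), end = as.integer(end))
}

#' BioC passage
#'
#' @param offset 0-based character offset of the passage within the document
#'   text.
#' @param text passage text.
#' @param passage_type one of `"title"`, `"paragraph"`, `"table"`,
#'   `"table_caption"`.
#' @param annotations data.frame with integer columns `row`, `col`, `start`,
#'   `end` (cell annotations; required for table passages).
#' @param infons named character vector of free metadata (stored sorted by
#'   key; reserved keys are rejected).
#' @return An object of class `bioc_passage`.
#' @export
bioc_passage <- function(offset, text, passage_type,
                         annotations = NULL, infons = NULL) {
  passage_type <- match.arg(passage_type, PASSAGE_TYPES)
  if (is.null(annotations))
    annotations <- new_cell_annotations(integer(0), integer(0),
                                        integer(0), integer(0))
  infons <- canonical_infons(infons)
  if (any(names(infons) %in% RESERVED_PASSAGE_INFONS))
    stop("reserved infon key in passage infons: ",
         paste(intersect(names(infons), RESERVED_PASSAGE_INFONS),
               collapse = ", "))
  structure(list(offset = as.integer(offset), text = as.character(text),
                 passage_type = passage_type,
                 annotations = annotations, infons = infons),
            class = "bioc_passage")
}

#' Validate a passage's annotation spans
#'
#' Every cell annotation's `[start, end)` span must lie within the passage
#' text; `(row, col)` pairs must be unique; carriage returns are rejected.
#'
#' @param p a `bioc_passage`.
#' @param where error-message context (e.g. which document/passage).
#' @return `p`, invisibly.
#' @export
validate_bioc_passage <- function(p, where = "") {
  a <- p$annotations
  n <- nchar(p$text)
  if (nrow(a) > 0) {
    bad <- a$start < 0L | a$end < a$start | a$end > n
    if (any(bad))
      stop("annotation span outside passage text", where,
           " (span [", a$start[which(bad)[1]], ",", a$end[which(bad)[1]],
           ") in text of length ", n, ")")
    if (anyDuplicated(a[c("row", "col")]))
      stop("duplicate (row, col) cell annotation", where)
  }
  if (grepl("\r", p$text, fixed = TRUE))
    stop("carriage return in passage text", where,
         " (unsupported: XML readers normalize line endings)")
  invisible(p)
}

#' BioC document
#'
#' @param doc_id article identifier plus source filename, e.g.
#'   `"PMC123456/table_s1.csv"`.
#' @param media_class one of the media classes (see [detect_media_class()]).
#' @param passages list of [bioc_passage()] objects with consistent offsets.
#' @param infons named character vector of document metadata (e.g. the
#'   original-file hyperlink or `conversion_status`).
#' @return An object of class `bioc_document`.
#' @export
bioc_document <- function(doc_id, media_class, passages = list(),
                          infons = NULL) {
  media_class <- match.arg(media_class, MEDIA_CLASSES)
  infons <- canonical_infons(infons)
  if (any(names(infons) %in% RESERVED_DOC_INFONS))
    stop("reserved infon key in document infons")
  structure(list(doc_id = as.character(doc_id), media_class = media_class,
                 passages = passages, infons = infons),
            class = "bioc_document")
}

#' Validate a document's passage offsets and table invariants
#'
#' Offsets must match the newline-separated concatenation of passage texts;
#' each table passage must carry exactly `n_rows * n_cols` cell annotations
#' whose spans reproduce a valid grid.
#'
#' @param d a `bioc_document`.
#' @return `d`, invisibly; errors name the document and passage.
#' @export
validate_bioc_document <- function(d) {
  off <- 0L
  for (i in seq_along(d$passages)) {
    p <- d$passages[[i]]
    where <- sprintf(" in document '%s', passage %d", d$doc_id, i)
    validate_bioc_passage(p, where)
    if (p$offset != off)
      stop("passage offset ", p$offset, " != expected ", off, where)
    if (p$passage_type == "table") {
      tab <- passage_table(p, check = TRUE, where = where)
      validate_sm_table(tab)
    }
    off <- off + nchar(p$text) + 1L
  }
  invisible(d)
}

#' BioC collection
#'
#' @param documents list of [bioc_document()] objects.
#' @param source,key collection-level metadata strings.
#' @param date collection date string (empty by default so that output is
#'   deterministic).
#' @return An object of class `bioc_collection`.
#' @export
bioc_collection <- function(documents = list(), source = "suppbioc",
                            date = "", key = "suppbioc.key") {
  structure(list(source = as.character(source), date = as.character(date),
                 key = as.character(key), documents = documents),
            class = "bioc_collection")
}

#' Validate every document in a collection
#'
#' @param x a `bioc_collection`.
#' @return `x`, invisibly.
#' @export
validate_bioc_collection <- function(x) {
  stopifnot(inherits(x, "bioc_collection"))
  for (d in x$documents) validate_bioc_document(d)
  invisible(x)
}

#' @export
print.bioc_collection <- function(x, ...) {
  cat("<bioc_collection> ", length(x$documents), " document(s)\n", sep = "")
  invisible(x)
}

#' @export
print.bioc_document <- function(x, ...) {
  cat("<bioc_document> ", x$doc_id, " [", x$media_class, "], ",
      length(x$passages), " passage(s)\n", sep = "")
  invisible(x)
}

# ---- table <-> passage -------------------------------------------------------

#' Encode an sm_table as a table passage (plus optional caption passage)
#'
#' The table passage's text is the TAB/NEWLINE linearization of the grid and
#' each cell carries an annotation with its row, column and character span
#' (zero-length spans for empty cells). If the table has a caption, a
#' `table_caption` passage linked by the `caption_for` infon precedes it.
#'
#' @param tab an [sm_table()].
#' @param offset document offset of the first emitted passage.
#' @return List of 1 or 2 `bioc_passage` objects.
#' @export
table_passages <- function(tab, offset = 0L) {
  validate_sm_table(tab)
  offset <- as.integer(offset)
  out <- list()
  if (!is.null(tab$caption)) {
    cap <- bioc_passage(offset, tab$caption, "table_caption",
                        infons = c(caption_for = tab$table_id))
    out <- c(out, list(cap))
    offset <- offset + nchar(tab$caption) + 1L
  }
  nr <- tab$n_rows; nc <- tab$n_cols
  if (nr == 0L) {
    text <- ""
    ann <- new_cell_annotations(integer(0), integer(0), integer(0), integer(0))
  } else {
    w <- nchar(tab$cells)
    # separator after each cell: TAB within a row, NEWLINE after each row but
    # the last, nothing after the final cell
    sep <- rep(1L, nr * nc)
    sep[nr * nc] <- 0L
    start <- cumsum(c(0L, (w + sep)[-(nr * nc)]))
    rows <- rep(seq_len(nr) - 1L, each = nc)
    cols <- rep(seq_len(nc) - 1L, times = nr)
    rowtexts <- vapply(seq_len(nr) - 1L, function(r)
      paste(tab$cells[rows == r], collapse = "\t"), "")
    text <- paste(rowtexts, collapse = "\n")
    ann <- new_cell_annotations(rows, cols, start, start + w)
  }
  p <- bioc_passage(offset, text, "table", annotations = ann)
  p <- set_table_infons(p, tab)
  c(out, list(p))
}

set_table_infons <- function(p, tab) {
  p$table_id <- tab$table_id
  p$n_rows <- tab$n_rows
  p$n_cols <- tab$n_cols
  p$source_sheet <- tab$source_sheet
  p
}

#' Reconstruct the sm_table stored in a table passage
#'
#' Cells are reassembled from the passage's cell annotations (never by
#' splitting the text, so cells containing tabs or newlines survive).
#'
#' @param p a `bioc_passage` of type `"table"`.
#' @param check validate spans against the passage text.
#' @param where error-message context.
#' @return An [sm_table()] (caption not attached; captions live in their own
#'   passages).
#' @export
passage_table <- function(p, check = TRUE, where = "") {
  if (p$passage_type != "table") stop("not a table passage", where)
  a <- p$annotations
  nr <- as.integer(p$n_rows); nc <- as.integer(p$n_cols)
  if (is.null(nr) || is.null(nc) || is.na(nr) || is.na(nc))
    stop("table passage missing n_rows/n_cols", where)
  if (nrow(a) != nr * nc)
    stop("table passage has ", nrow(a), " cell annotations for a ",
         nr, "x", nc, " grid", where)
  if (check && nrow(a) > 0) {
    if (any(a$end > nchar(p$text)) || any(a$start < 0L) || any(a$end < a$start))
      stop("cell annotation span outside passage text", where)
  }
  cells <- character(nr * nc)
  if (nrow(a) > 0) {
    val <- substring(p$text, a$start + 1L, a$end)
    cells[a$row * nc + a$col + 1L] <- val
  }
  sm_table(cells, nr, nc, p$table_id, source_sheet = p$source_sheet)
}

#' Assemble a document from ordered content items
#'
#' Items are `sm_table` objects or character strings (paragraphs); offsets are
#' computed per the newline-separated concatenation convention. The first
#' character item may be flagged a title via `title_first`.
#'
#' @param doc_id,media_class,infons as in [bioc_document()].
#' @param items list of `sm_table` objects and character scalars, in source
#'   order.
#' @param title_first treat the first character item as the document title.
#' @return A validated [bioc_document()].
#' @export
build_document <- function(doc_id, media_class, items, infons = NULL,
                           title_first = FALSE) {
  passages <- list()
  offset <- 0L
  seen_text <- FALSE
  for (it in items) {
    if (inherits(it, "sm_table")) {
      ps <- table_passages(it, offset)
      passages <- c(passages, ps)
      last <- ps[[length(ps)]]
      offset <- last$offset + nchar(last$text) + 1L
      seen_text <- TRUE
    } else if (is.character(it) && length(it) == 1L) {
      type <- if (title_first && !seen_text) "title" else "paragraph"
      passages <- c(passages, list(bioc_passage(offset, it, type)))
      offset <- offset + nchar(it) + 1L
      seen_text <- TRUE
    } else stop("items must be sm_table objects or character scalars")
  }
  d <- bioc_document(doc_id, media_class, passages, infons)
  validate_bioc_document(d)
  d
}

#' Extract every table from a document or collection
#'
#' Captions stored in adjacent `table_caption` passages are re-attached to the
#' returned `sm_table` objects.
#'
#' @param x a `bioc_document` or `bioc_collection`.
#' @return List of [sm_table()] objects in passage order.
#' @export
document_tables <- function(x) {
  if (inherits(x, "bioc_collection"))
    return(unlist(lapply(x$documents, document_tables), recursive = FALSE))
  stopifnot(inherits(x, "bioc_document"))
  out <- list()
  caps <- list()  # table_id -> caption text
  for (p in x$passages) {
    if (p$passage_type == "table_caption") {
      caps[[p$infons[["caption_for"]]]] <- p$text
    } else if (p$passage_type == "table") {
      tab <- passage_table(p)
      if (!is.null(caps[[tab$table_id]])) tab$caption <- caps[[tab$table_id]]
      out <- c(out, list(tab))
    }
  }
  out
}
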