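# RFC-4180 delimited-text parsing with delimiter sniffing. Implemented from
# scratch (the parsing policy — sniffing, ragged-row padding — is part of the
# package contract); base read.csv serves only as an independent oracle in the
# test suite.

SNIFF_DELIMS <- c(",", "\t", ";")

#' Parse delimited text into a list of row vectors
#'
#' RFC-4180 quoting: fields may be double-quoted; quoted fields may contain
#' the delimiter, newlines and doubled (`""`) quotes. Rows are not padded
#' here — see [extract_delimited()].
#'
#' @param text character scalar.
#' @param delim single-character delimiter.
#' @return List of character vectors, one per record.
#' @export
parse_delimited <- function(text, delim) {
  stopifnot(is.character(text), length(text) == 1, nchar(delim) == 1)
  if (!nzchar(text)) return(list())
  if (!grepl("\"", text, fixed = TRUE)) {
    # fast path: no quoting anywhere; sentinel keeps trailing blank records
    body <- gsub("\r", "", sub("\n$", "", text), fixed = TRUE)
    if (!nzchar(body)) return(list(""))
    lines <- strsplit(paste0(body, "\n\x01"), "\n", fixed = TRUE)[[1]]
    lines <- lines[-length(lines)]
    return(strsplit(paste0(lines, delim), delim, fixed = TRUE))
  }
  chars <- strsplit(text, "")[[1]]
  rows <- list(); fields <- character(0)
  buf <- character(0); in_quotes <- FALSE
  i <- 1L; n <- length(chars)
  flush_field <- function() {
    fields <<- c(fields, paste(buf, collapse = ""))
    buf <<- character(0)
  }
  while (i <= n) {
    ch <- chars[i]
    if (in_quotes) {
      if (ch == "\"") {
        if (i < n && chars[i + 1L] == "\"") { buf <- c(buf, "\""); i <- i + 1L }
        else in_quotes <- FALSE
      } else buf <- c(buf, ch)
    } else if (ch == "\"") {
      in_quotes <- TRUE
    } else if (ch == delim) {
      flush_field()
    } else if (ch == "\n") {
      flush_field()
      rows[[length(rows) + 1L]] <- fields
      fields <- character(0)
    } else if (ch != "\r") {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  if (length(buf) > 0 || length(fields) > 0 || n == 0 ||
      chars[n] != "\n" || in_quotes) {
    flush_field()
    rows[[length(rows) + 1L]] <- fields
  }
  rows
}

#' Sniff the delimiter of a delimited-text payload
#'
#' Candidates are comma, tab and semicolon; the winner maximizes the
#' consistent (modal) column count over the first 20 records, preferring more
#' consistent rows, then more columns, then candidate order.
#'
#' @param text character scalar.
#' @return Single-character delimiter.
#' @export
sniff_delimiter <- function(text) {
  best <- SNIFF_DELIMS[1]; best_score <- c(-1, -1)
  for (d in SNIFF_DELIMS) {
    rows <- parse_delimited(text, d)
    rows <- rows[seq_len(min(20L, length(rows)))]
    counts <- lengths(rows)
    if (length(counts) == 0) next
    modal <- as.integer(names(which.max(table(counts))))
    if (modal < 2) next  # a "delimiter" that never splits carries no signal
    score <- c(sum(counts == modal), modal)
    if (score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2])) {
      best <- d; best_score <- score
    }
  }
  best
}

#' Extract a table from delimited or plain text
#'
#' Decodes the payload (UTF-8, then Latin-1 fallback), sniffs the delimiter,
#' parses with RFC-4180 quoting, and right-pads ragged rows with empty cells
#' so that `n_cols` is the maximum record length.
#'
#' @param payload raw vector (or an already-decoded character scalar).
#' @param table_id identifier for the resulting table.
#' @param encoding_hint optional encoding to try before the default cascade.
#' @return An [sm_table()]; undecodable bytes raise a
#'   `suppbioc_conversion_error` (recorded, not fatal, in [convert_corpus()]).
#' @examples
#' extract_delimited(charToRaw("a,b\n1,2"))$cells
#' @export
extract_delimited <- function(payload, table_id = "t1", encoding_hint = NULL) {
  text <- if (is.character(payload)) payload else {
    if (!is.null(encoding_hint)) {
      dec <- tryCatch(iconv(rawToChar(payload), encoding_hint, "UTF-8"),
                      error = function(e) NA_character_)
      if (!is.na(dec)) dec else decode_payload(payload)
    } else decode_payload(payload)
  }
  delim <- sniff_delimiter(text)
  rows <- parse_delimited(text, delim)
  rows_to_table(rows, table_id)
}

rows_to_table <- function(rows, table_id, source_sheet = NULL, caption = NULL) {
  if (length(rows) == 0)
    return(sm_table(character(0), 0, 0, table_id, caption = caption,
                    source_sheet = source_sheet))
  nc <- max(lengths(rows))
  cells <- unlist(lapply(rows, function(r) c(r, rep("", nc - length(r)))))
  sm_table(cells, length(rows), nc, table_id, caption = caption,
           source_sheet = source_sheet)
}
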