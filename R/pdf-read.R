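# Best-effort text extraction from PDFs with uncompressed content streams
# (the kind the synthetic generator writes). Tables are NEVER reconstructed
# from PDF input — tabular content comes out as raw text only, matching the
# pipeline's stated PDF limitation. FlateDecode/encrypted/truncated PDFs are
# reported as conversion failures.

#' Extract raw text paragraphs from a PDF
#'
#' Scans uncompressed content streams in document order and emits one
#' paragraph per `Tj`/`TJ` text-showing operator. No table objects are ever
#' produced from PDF input.
#'
#' @param payload raw vector of PDF bytes.
#' @return Character vector of paragraphs (empty for a zero-page PDF).
#' @export
extract_pdf_text <- function(payload) {
  if (!is_pdf_payload(payload))
    conversion_error("not a PDF: bad signature")
  txt <- rawToChar(payload[payload != as.raw(0)])
  Encoding(txt) <- "latin1"
  if (!grepl("%%EOF", txt, fixed = TRUE))
    conversion_error("truncated PDF: missing %%EOF trailer")
  if (grepl("/Encrypt", txt, fixed = TRUE))
    conversion_error("encrypted PDF")
  streams <- extract_pdf_streams(txt)
  out <- character(0)
  for (s in streams) {
    if (grepl("FlateDecode", attr(s, "dict"), fixed = TRUE))
      conversion_error("compressed (FlateDecode) PDF stream: unsupported")
    if (!grepl("BT", s, fixed = TRUE)) next
    out <- c(out, pdf_stream_text(s))
  }
  enc2utf8(out)
}

extract_pdf_streams <- function(txt) {
  starts <- gregexpr("(?<!end)stream\r?\n", txt, perl = TRUE)[[1]]
  if (starts[1] == -1) return(list())
  ends <- gregexpr("endstream", txt, fixed = TRUE)[[1]]
  lens <- attr(starts, "match.length")
  out <- list()
  for (i in seq_along(starts)) {
    e <- ends[ends > starts[i]]
    if (length(e) == 0)
      conversion_error("truncated PDF: unterminated stream")
    body <- substr(txt, starts[i] + lens[i], e[1] - 1L)
    # the stream dictionary sits just before the 'stream' keyword
    dict <- substr(txt, max(1L, starts[i] - 300L), starts[i] - 1L)
    dict <- sub(".*<<", "<<", dict)
    attr(body, "dict") <- dict
    out <- c(out, list(body))
  }
  out
}

pdf_stream_text <- function(s) {
  # one paragraph per Tj; a TJ array is one paragraph with its strings joined
  ops <- gregexpr("(\\((?:[^()\\\\]|\\\\.)*\\)\\s*Tj)|(\\[[^]]*\\]\\s*TJ)",
                  s, perl = TRUE)[[1]]
  if (ops[1] == -1) return(character(0))
  pieces <- regmatches(s, list(ops))[[1]]
  vapply(pieces, function(p) {
    strs <- regmatches(p,
      gregexpr("\\((?:[^()\\\\]|\\\\.)*\\)", p, perl = TRUE))[[1]]
    paste(vapply(strs, pdf_unescape_string, ""), collapse = "")
  }, "", USE.NAMES = FALSE)
}

pdf_unescape_string <- function(x) {
  x <- substr(x, 2, nchar(x) - 1L)  # strip parentheses
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  # single left-to-right pass so a literal backslash never re-triggers
  toks <- regmatches(x, gregexpr("\\\\.|[^\\\\]", x))[[1]]
  esc <- c(n = "\n", r = "\r", t = "\t", "(" = "(", ")" = ")", "\\" = "\\")
  paste(vapply(toks, function(tk) {
    if (nchar(tk) == 2 && substr(tk, 1, 1) == "\\") {
      s <- substr(tk, 2, 2)
      if (s %in% names(esc)) esc[[s]] else s
    } else tk
  }, "", USE.NAMES = FALSE), collapse = "")
}
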