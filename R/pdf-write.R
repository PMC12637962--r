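# Minimal single-page (or zero-page) text PDF writer: uncompressed content
# streams, one Tj operator per paragraph, correct xref table. No renderer is
# needed; the matching extractor is in pdf-read.R.

pdf_escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("(", "\\(", x, fixed = TRUE)
  x <- gsub(")", "\\)", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

#' Write a minimal text PDF
#'
#' Emits a valid single-page PDF with one `Tj` text-showing operator per
#' paragraph in an uncompressed content stream, or a valid zero-page PDF when
#' `paragraphs` is empty. Only Latin-1-representable text is supported (the
#' PDF standard encoding); other characters are transliterated to `?`.
#'
#' @param paragraphs character vector of paragraph texts.
#' @return Raw vector holding the PDF bytes.
#' @export
write_pdf_raw <- function(paragraphs) {
  paragraphs <- as.character(paragraphs)
  objs <- character(0)
  if (length(paragraphs) == 0) {
    objs <- c("<< /Type /Catalog /Pages 2 0 R >>",
              "<< /Type /Pages /Kids [] /Count 0 >>")
  } else {
    latin <- iconv(paragraphs, "UTF-8", "latin1", sub = "?")
    shows <- sprintf("(%s) Tj T*", pdf_escape_string(latin))
    stream <- paste0("BT /F1 11 Tf 14 TL 72 720 Td\n",
                     paste(shows, collapse = "\n"), "\nET")
    objs <- c("<< /Type /Catalog /Pages 2 0 R >>",
              "<< /Type /Pages /Kids [3 0 R] /Count 1 >>",
              paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] ",
                     "/Contents 4 0 R /Resources << /Font << /F1 5 0 R >> >> >>"),
              sprintf("<< /Length %d >>\nstream\n%s\nendstream",
                      nchar(stream, type = "bytes"), stream),
              "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>")
  }
  header <- "%PDF-1.4\n"
  body <- character(length(objs))
  offsets <- integer(length(objs))
  pos <- nchar(header, type = "bytes")
  for (i in seq_along(objs)) {
    body[i] <- sprintf("%d 0 obj\n%s\nendobj\n", i, objs[i])
    offsets[i] <- pos
    pos <- pos + nchar(body[i], type = "bytes")
  }
  xref_pos <- pos
  xref <- paste0("xref\n0 ", length(objs) + 1, "\n",
                 "0000000000 65535 f \n",
                 paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"),
                 "\n")
  trailer <- sprintf("trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
                     length(objs) + 1, xref_pos)
  out <- paste0(header, paste(body, collapse = ""), xref, trailer)
  # latin1 bytes so stream /Length matches what was declared
  charToRaw(iconv(out, "UTF-8", "latin1", sub = "?"))
}
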