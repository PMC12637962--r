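# Media-class detection and text decoding.

EXT_CLASS <- c(
  csv = "delimited_text", tsv = "delimited_text", tab = "delimited_text",
  txt = "plain_text", text = "plain_text",
  xlsx = "spreadsheet", xlsm = "spreadsheet", xls = "spreadsheet",
  docx = "word_processor", doc = "word_processor",
  pptx = "slides", ppt = "slides",
  pdf = "pdf",
  zip = "archive", tar = "archive", gz = "archive", tgz = "archive",
  # common binary supplementary formats (e.g. .sav, IBM SPSS data)
  sav = "non_textual", jpg = "non_textual", jpeg = "non_textual",
  png = "non_textual", gif = "non_textual", tif = "non_textual",
  tiff = "non_textual", bmp = "non_textual", mp4 = "non_textual",
  avi = "non_textual", mov = "non_textual", wav = "non_textual",
  mp3 = "non_textual", rds = "non_textual", rdata = "non_textual",
  exe = "non_textual", bin = "non_textual", fig = "non_textual")

magic_class <- function(payload) {
  if (is_zip_payload(payload) || is_gzip_payload(payload)) return("archive")
  if (is_pdf_payload(payload)) return("pdf")
  NA_character_
}

#' Classify a supplementary file by extension and magic bytes
#'
#' Extension rules apply first; magic bytes act as tiebreak/fallback: a
#' text-like extension whose bytes carry a ZIP/gzip/PDF signature is
#' reclassified by the signature (OOXML extensions legitimately carry the ZIP
#' signature and are kept). Unknown extensions with undecodable content are
#' `non_textual`. Total function: never errors.
#'
#' @param filename file name (extension may be compound, e.g. `.tar.gz`).
#' @param payload raw vector of file bytes.
#' @return One of `"delimited_text"`, `"plain_text"`, `"spreadsheet"`,
#'   `"word_processor"`, `"slides"`, `"pdf"`, `"archive"`, `"non_textual"`.
#' @examples
#' detect_media_class("table_s1.csv", charToRaw("a,b\n1,2"))
#' @export
detect_media_class <- function(filename, payload = raw(0)) {
  stopifnot(nzchar(filename))
  ext <- tolower(tools::file_ext(filename))
  by_ext <- if (nzchar(ext) && ext %in% names(EXT_CLASS)) EXT_CLASS[[ext]]
            else NA_character_
  by_magic <- magic_class(payload)
  if (!is.na(by_ext)) {
    # signature overrides only text-like extension claims
    if (!is.na(by_magic) &&
        by_ext %in% c("delimited_text", "plain_text", "non_textual"))
      return(by_magic)
    return(by_ext)
  }
  if (!is.na(by_magic)) return(by_magic)
  if (length(payload) > 0 && is_decodable_text(payload)) return("plain_text")
  "non_textual"
}

#' Decode raw bytes to text
#'
#' Tries UTF-8 first, then a byte-level binary screen, then Latin-1 as a last
#' resort; the chosen encoding is attached as the `"encoding"` attribute.
#'
#' @param payload raw vector.
#' @return Character scalar (UTF-8) with attribute `encoding`, or an error of
#'   class `suppbioc_decode_error` for binary content.
#' @export
decode_payload <- function(payload) {
  if (length(payload) == 0)
    return(structure("", encoding = "UTF-8"))
  if (!is_decodable_text(payload))
    stop(errorCondition("binary (undecodable) content",
                        class = c("suppbioc_decode_error",
                                  "suppbioc_conversion_error", "error")))
  s <- rawToChar(payload)
  if (all(validUTF8(s))) {
    Encoding(s) <- "UTF-8"
    structure(enc2utf8(s), encoding = "UTF-8")
  } else {
    Encoding(s) <- "latin1"
    structure(enc2utf8(s), encoding = "latin1")
  }
}

is_decodable_text <- function(payload) {
  if (any(payload == as.raw(0))) return(FALSE)
  n <- length(payload)
  ctrl <- sum(payload < as.raw(9) | (payload > as.raw(13) & payload < as.raw(32)))
  ctrl / n < 0.02
}
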