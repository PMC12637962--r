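# BioC-XML codec. The writer is a deterministic string builder (same model in,
# byte-identical text out — a contract the tests assert); the reader uses xml2.

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x <- gsub("\t", "&#9;", x, fixed = TRUE)
  gsub("\n", "&#10;", x, fixed = TRUE)
}

infon_lines <- function(infons, indent) {
  if (length(infons) == 0L) return(character(0))
  sprintf("%s<infon key=\"%s\">%s</infon>", indent,
          xml_escape_attr(names(infons)), xml_escape_text(unname(infons)))
}

passage_reserved_infons <- function(p) {
  inf <- c(type = p$passage_type)
  if (p$passage_type == "table") {
    inf <- c(inf, table_id = p$table_id,
             n_rows = as.character(p$n_rows), n_cols = as.character(p$n_cols))
    if (!is.null(p$source_sheet)) inf <- c(inf, source_sheet = p$source_sheet)
  }
  inf
}

#' Serialize a collection to BioC-XML
#'
#' Produces well-formed UTF-8 XML over the BioC element vocabulary
#' (`collection`/`document`/`passage`/`annotation`/`infon`); the cell grid of
#' every table passage is encoded as annotations with `row`/`col` infons and
#' passage-relative character spans. Output is deterministic: infons are
#' written in canonical (reserved-then-sorted) order, so writing the same
#' collection twice yields byte-identical text.
#'
#' @param collection a [bioc_collection()] (a plain list of documents is
#'   wrapped).
#' @return A single UTF-8 string.
#' @seealso [read_bioc_xml()], [write_bioc_json()]
#' @export
write_bioc_xml <- function(collection) {
  if (!inherits(collection, "bioc_collection"))
    collection <- bioc_collection(collection)
  validate_bioc_collection(collection)
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           "<collection>",
           sprintf("  <source>%s</source>", xml_escape_text(collection$source)),
           sprintf("  <date>%s</date>", xml_escape_text(collection$date)),
           sprintf("  <key>%s</key>", xml_escape_text(collection$key)))
  for (d in collection$documents) out <- c(out, write_xml_document(d))
  out <- c(out, "</collection>", "")
  enc2utf8(paste(out, collapse = "\n"))
}

write_xml_document <- function(d) {
  out <- c("  <document>",
           sprintf("    <id>%s</id>", xml_escape_text(d$doc_id)),
           infon_lines(c(media_class = d$media_class), "    "),
           infon_lines(d$infons, "    "))
  for (p in d$passages) out <- c(out, write_xml_passage(p))
  c(out, "  </document>")
}

write_xml_passage <- function(p) {
  out <- c("    <passage>",
           infon_lines(passage_reserved_infons(p), "      "),
           infon_lines(p$infons, "      "),
           sprintf("      <offset>%d</offset>", p$offset),
           sprintf("      <text>%s</text>", xml_escape_text(p$text)))
  a <- p$annotations
  if (nrow(a) > 0) {
    cell_text <- substring(p$text, a$start + 1L, a$end)
    out <- c(out, sprintf(paste0(
      "      <annotation id=\"r%dc%d\">\n",
      "        <infon key=\"type\">cell</infon>\n",
      "        <infon key=\"row\">%d</infon>\n",
      "        <infon key=\"col\">%d</infon>\n",
      "        <location offset=\"%d\" length=\"%d\"/>\n",
      "        <text>%s</text>\n",
      "      </annotation>"),
      a$row, a$col, a$row, a$col, a$start, a$end - a$start,
      xml_escape_text(cell_text)))
  }
  c(out, "    </passage>")
}

#' Parse BioC-XML into a collection
#'
#' Inverse of [write_bioc_xml()]: table grids are rebuilt from cell
#' annotations and unknown infons are preserved verbatim. Malformed XML
#' raises the parser's error (with line number); annotation spans outside
#' their passage text raise a validation error.
#'
#' @param text XML as a single string, or a file path.
#' @return A [bioc_collection()].
#' @export
read_bioc_xml <- function(text) {
  doc <- xml2::read_xml(text)
  if (xml2::xml_name(doc) != "collection") stop("root element is not <collection>")
  getel <- function(node, name) {
    n <- xml2::xml_find_first(node, name)
    if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
  }
  docs <- lapply(xml2::xml_find_all(doc, "document"), read_xml_document)
  coll <- bioc_collection(docs, source = getel(doc, "source"),
                          date = getel(doc, "date"), key = getel(doc, "key"))
  validate_bioc_collection(coll)
  coll
}

read_infons <- function(node) {
  nodes <- xml2::xml_find_all(node, "infon")
  vals <- xml2::xml_text(nodes)
  names(vals) <- xml2::xml_attr(nodes, "key")
  vals
}

read_xml_document <- function(node) {
  infons <- read_infons(node)
  media <- infons[["media_class"]]
  infons <- infons[setdiff(names(infons), RESERVED_DOC_INFONS)]
  passages <- lapply(xml2::xml_find_all(node, "passage"), read_xml_passage)
  bioc_document(xml2::xml_text(xml2::xml_find_first(node, "id")),
                media, passages, infons)
}

read_xml_passage <- function(node) {
  infons <- read_infons(node)
  type <- infons[["type"]]
  anns <- xml2::xml_find_all(node, "annotation")
  if (length(anns) > 0) {
    ai <- lapply(anns, read_infons)
    loc <- xml2::xml_find_first(anns, "location")
    off <- as.integer(xml2::xml_attr(loc, "offset"))
    len <- as.integer(xml2::xml_attr(loc, "length"))
    ann <- new_cell_annotations(
      row = as.integer(vapply(ai, `[[`, "", "row")),
      col = as.integer(vapply(ai, `[[`, "", "col")),
      start = off, end = off + len)
  } else ann <- NULL
  p <- bioc_passage(
    offset = as.integer(xml2::xml_text(xml2::xml_find_first(node, "offset"))),
    text = xml2::xml_text(xml2::xml_find_first(node, "text")),
    passage_type = type, annotations = ann,
    infons = infons[setdiff(names(infons), RESERVED_PASSAGE_INFONS)])
  if (type == "table") {
    p$table_id <- infons[["table_id"]]
    p$n_rows <- as.integer(infons[["n_rows"]])
    p$n_cols <- as.integer(infons[["n_cols"]])
    if ("source_sheet" %in% names(infons))
      p$source_sheet <- infons[["source_sheet"]]
  }
  p
}
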