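# BioC-JSON codec: same data model as the XML codec, mutually convertible
# with no loss, so XML -> model -> JSON -> model -> XML is byte-identical.

named_obj <- function(x) {
  if (length(x) == 0L) return(structure(list(), names = character(0)))
  as.list(x)
}

#' Serialize a collection to BioC-JSON
#'
#' Same data model and canonical infon ordering as [write_bioc_xml()];
#' annotations carry `locations` entries with passage-relative `offset` and
#' `length`. Cells containing tabs, newlines or quotes survive round-trip via
#' JSON string escaping.
#'
#' @inheritParams write_bioc_xml
#' @return A single UTF-8 JSON string.
#' @export
write_bioc_json <- function(collection) {
  if (!inherits(collection, "bioc_collection"))
    collection <- bioc_collection(collection)
  validate_bioc_collection(collection)
  x <- list(source = collection$source, date = collection$date,
            key = collection$key,
            documents = lapply(collection$documents, json_document))
  paste0(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                          pretty = FALSE, null = "null"), "\n")
}

json_document <- function(d) {
  list(id = d$doc_id,
       infons = named_obj(c(c(media_class = d$media_class), d$infons)),
       passages = lapply(d$passages, json_passage))
}

json_passage <- function(p) {
  a <- p$annotations
  anns <- list()
  if (nrow(a) > 0) {
    cell_text <- substring(p$text, a$start + 1L, a$end)
    anns <- lapply(seq_len(nrow(a)), function(i) {
      list(id = sprintf("r%dc%d", a$row[i], a$col[i]),
           infons = list(type = "cell", row = as.character(a$row[i]),
                         col = as.character(a$col[i])),
           text = cell_text[i],
           locations = list(list(offset = a$start[i],
                                 length = a$end[i] - a$start[i])))
    })
  }
  list(infons = named_obj(c(passage_reserved_infons(p), p$infons)),
       offset = p$offset, text = p$text, annotations = anns)
}

#' Parse BioC-JSON into a collection
#'
#' @param text JSON as a single string.
#' @return A [bioc_collection()].
#' @export
read_bioc_json <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  docs <- lapply(x$documents, function(jd) {
    infons <- unlist(jd$infons) %||% character(0)
    bioc_document(jd$id, infons[["media_class"]],
                  lapply(jd$passages, json_read_passage),
                  infons[setdiff(names(infons), RESERVED_DOC_INFONS)])
  })
  coll <- bioc_collection(docs, source = x$source %||% "",
                          date = x$date %||% "", key = x$key %||% "")
  validate_bioc_collection(coll)
  coll
}

json_read_passage <- function(jp) {
  infons <- unlist(jp$infons) %||% character(0)
  type <- infons[["type"]]
  ann <- NULL
  if (length(jp$annotations) > 0) {
    off <- vapply(jp$annotations, function(a) a$locations[[1]]$offset, 0)
    len <- vapply(jp$annotations, function(a) a$locations[[1]]$length, 0)
    ann <- new_cell_annotations(
      row = as.integer(vapply(jp$annotations, function(a) a$infons$row, "")),
      col = as.integer(vapply(jp$annotations, function(a) a$infons$col, "")),
      start = off, end = off + len)
  }
  p <- bioc_passage(jp$offset, jp$text, type, annotations = ann,
                    infons = infons[setdiff(names(infons),
                                            RESERVED_PASSAGE_INFONS)])
  if (type == "table") {
    p$table_id <- infons[["table_id"]]
    p$n_rows <- as.integer(infons[["n_rows"]])
    p$n_cols <- as.integer(infons[["n_cols"]])
    if ("source_sheet" %in% names(infons))
      p$source_sheet <- infons[["source_sheet"]]
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
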