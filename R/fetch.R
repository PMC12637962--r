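# BioC fetch: return all converted supplementary documents for a batch of
# article ids, honouring the service limits (at most 50 ids per request;
# responses above 5 MB of serialized UTF-8 are flagged as attachments).

MAX_IDS_PER_REQUEST <- 50L
ATTACHMENT_BYTES <- 5L * 1024L * 1024L

#' Fetch converted supplementary documents by article id
#'
#' @param corpus_store a [bioc_collection()] holding the converted corpus
#'   (document ids are `article_id/filename`).
#' @param ids character vector of PMIDs/PMCIDs (opaque keys), 1 to 50 of
#'   them; more raises a request-rejected error.
#' @param attachment_bytes size threshold for the attachment flag.
#' @return Named list (by id). Each element: `found` (logical), and when
#'   found `collection` (the id's documents as a [bioc_collection()]),
#'   `body` (its BioC-JSON serialization), `size_bytes`, `attachment`
#'   (TRUE when `size_bytes` exceeds the threshold). Unknown ids give
#'   `found = FALSE` markers; known ids are still returned.
#' @export
fetch_sm <- function(corpus_store, ids,
                     attachment_bytes = ATTACHMENT_BYTES) {
  stopifnot(inherits(corpus_store, "bioc_collection"))
  if (length(ids) < 1)
    stop(errorCondition("at least one id is required",
                        class = c("suppbioc_bad_request", "error")))
  if (length(ids) > MAX_IDS_PER_REQUEST)
    stop(errorCondition(
      paste0("request rejected: ", length(ids), " ids exceed the limit of ",
             MAX_IDS_PER_REQUEST, " PMIDs or PMCIDs per request"),
      class = c("suppbioc_bad_request", "error")))
  doc_art <- vapply(corpus_store$documents, function(d)
    regmatches(d$doc_id, regexpr("/", d$doc_id), invert = TRUE)[[1]][1], "")
  out <- lapply(ids, function(id) {
    docs <- corpus_store$documents[doc_art == id]
    if (length(docs) == 0) return(list(found = FALSE))
    coll <- bioc_collection(docs)
    body <- write_bioc_json(coll)
    size <- nchar(body, type = "bytes")
    list(found = TRUE, collection = coll, body = body, size_bytes = size,
         attachment = size > attachment_bytes)
  })
  stats::setNames(out, ids)
}
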