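# Dispatch: one supplementary file -> one BioC document (archives -> one
# document per textual member), plus corpus-level accounting.

#' Convert one supplementary file to a BioC document
#'
#' Dispatches to the extractor for the file's media class and assembles
#' passages (paragraphs, captions, tables) in source order. Extractor
#' failures do not propagate: the result is a document with
#' `conversion_status = "failed"` and no passages. Plain-text payloads whose
#' sniffed structure has at least two columns are treated as delimited tables;
#' otherwise their lines become paragraphs.
#'
#' For `media_class = "archive"` the archive is expanded and a LIST of
#' documents is returned, one per textual member (non-textual members are
#' skipped); use [convert_corpus()] for flat accounting.
#'
#' @param file an [sm_file()].
#' @param max_depth,ceiling_bytes archive expansion controls
#'   (see [expand_archive()]).
#' @return A [bioc_document()], or a list of them for archives.
#' @export
convert_file <- function(file, max_depth = 3, ceiling_bytes = 2^30) {
  stopifnot(inherits(file, "sm_file"))
  if (file$media_class == "non_textual")
    stop("non-textual files are never passed to extractors: ", file$filename)
  if (file$media_class == "archive") {
    members <- expand_archive(file, max_depth = max_depth,
                              ceiling_bytes = ceiling_bytes)
    members <- Filter(function(m) m$media_class != "non_textual", members)
    return(lapply(members, convert_file))
  }
  doc_id <- paste0(file$article_id, "/", file$filename)
  base_infons <- c(source_filename = file$filename,
                   source_url = paste0("pmc://", file$article_id, "/",
                                       file$filename))
  tryCatch({
    items <- extract_items(file)
    d <- build_document(doc_id, file$media_class, items,
                        infons = c(base_infons, conversion_status = "success",
                                   encoding = attr(items, "encoding") %||%
                                     "UTF-8"))
    d
  }, suppbioc_conversion_error = function(e) {
    bioc_document(doc_id, file$media_class, list(),
                  infons = c(base_infons, conversion_status = "failed",
                             failure_reason = conditionMessage(e)))
  })
}

extract_items <- function(file) {
  cls <- file$media_class
  enc <- "UTF-8"
  items <- switch(cls,
    delimited_text = {
      text <- decode_payload(file$payload)
      enc <- attr(text, "encoding")
      list(extract_delimited(as.character(text), table_id = "t1"))
    },
    plain_text = {
      text <- decode_payload(file$payload)
      enc <- attr(text, "encoding")
      tab <- extract_delimited(as.character(text), table_id = "t1")
      if (tab$n_cols >= 2) list(tab)
      else as.list(parse_plain_paragraphs(as.character(text)))
    },
    spreadsheet = extract_spreadsheet(file$payload),
    word_processor = extract_wordproc(file$payload)$items,
    slides = extract_slides(file$payload)$items,
    pdf = as.list(extract_pdf_text(file$payload)),
    stop("no extractor for media class ", cls))
  structure(items, encoding = enc)
}

parse_plain_paragraphs <- function(text) {
  if (!nzchar(text)) return(character(0))
  lines <- strsplit(gsub("\r", "", text, fixed = TRUE), "\n",
                    fixed = TRUE)[[1]]
  lines[nzchar(lines)]
}

#' Conversion accounting
#'
#' @param outcomes data.frame with columns `filename` and `ok` (logical) and
#'   `reason`.
#' @return Object of class `conversion_report` with fields `n_total`,
#'   `n_converted`, `n_failed`, `failures` (data.frame) and `success_rate`
#'   (`1.0` for an empty corpus, by convention).
#' @export
conversion_report <- function(outcomes) {
  n_total <- nrow(outcomes)
  n_converted <- sum(outcomes$ok)
  n_failed <- n_total - n_converted
  structure(list(
    n_total = n_total, n_converted = n_converted, n_failed = n_failed,
    failures = outcomes[!outcomes$ok, c("filename", "reason"), drop = FALSE],
    success_rate = if (n_total > 0) n_converted / n_total else 1.0),
    class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("<conversion_report> %d/%d converted (%.2f%%), %d failed\n",
              x$n_converted, x$n_total, 100 * x$success_rate, x$n_failed))
  invisible(x)
}

#' Convert a corpus of supplementary files
#'
#' Files are processed in deterministic order (sorted by `article_id`, then
#' `filename`). Archives are expanded and each textual member is converted
#' and counted as its own file; non-textual files (and non-textual archive
#' members) are skipped and counted separately. Failures are data, never
#' errors.
#'
#' @param files list of [sm_file()] objects.
#' @param max_depth,ceiling_bytes archive expansion controls.
#' @return List with `documents` (list of [bioc_document()]) and `report`
#'   (a [conversion_report()]; `n_skipped` non-textual count attached as an
#'   attribute).
#' @export
convert_corpus <- function(files, max_depth = 3, ceiling_bytes = 2^30) {
  ord <- order(vapply(files, `[[`, "", "article_id"),
               vapply(files, `[[`, "", "filename"), method = "radix")
  files <- files[ord]
  docs <- list()
  fn <- character(0); ok <- logical(0); reason <- character(0)
  n_skipped <- 0L
  note <- function(d) {
    st <- d$infons[["conversion_status"]]
    fn <<- c(fn, d$infons[["source_filename"]])
    ok <<- c(ok, identical(st, "success"))
    reason <<- c(reason, if (identical(st, "success")) ""
                 else d$infons[["failure_reason"]])
    docs[[length(docs) + 1L]] <<- d
  }
  for (f in files) {
    if (f$media_class == "non_textual") { n_skipped <- n_skipped + 1L; next }
    if (f$media_class == "archive") {
      res <- tryCatch(convert_file(f, max_depth, ceiling_bytes),
                      error = function(e) e)
      if (inherits(res, "error")) {
        # the archive itself failed to expand: counted once, as failed
        fn <- c(fn, f$filename); ok <- c(ok, FALSE)
        reason <- c(reason, conditionMessage(res))
      } else for (d in res) note(d)
    } else {
      note(convert_file(f))
    }
  }
  report <- conversion_report(data.frame(filename = fn, ok = ok,
                                         reason = reason,
                                         stringsAsFactors = FALSE))
  attr(report, "n_skipped") <- n_skipped
  list(documents = docs, report = report)
}
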