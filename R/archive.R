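# Archive expansion: ZIP / TAR / GZ, recursive up to a depth limit, with a
# total-bytes ceiling guarding against archive bombs.

#' Supplementary file handle
#'
#' @param article_id PMID/PMCID-style identifier (opaque key).
#' @param filename file name (members of archives carry the archive path as
#'   prefix, e.g. `"data.zip/table.csv"`).
#' @param payload raw vector of file bytes.
#' @param media_class optional; detected from `filename`/`payload` if absent.
#' @return Object of class `sm_file`.
#' @export
sm_file <- function(article_id, filename, payload, media_class = NULL) {
  stopifnot(is.raw(payload))
  if (is.null(media_class)) media_class <- detect_media_class(filename, payload)
  else media_class <- match.arg(media_class, MEDIA_CLASSES)
  structure(list(article_id = as.character(article_id),
                 filename = as.character(filename),
                 payload = payload, media_class = media_class,
                 size_bytes = length(payload)),
            class = "sm_file")
}

#' @export
print.sm_file <- function(x, ...) {
  cat("<sm_file> ", x$article_id, "/", x$filename, " [", x$media_class, ", ",
      x$size_bytes, " bytes]\n", sep = "")
  invisible(x)
}

#' Expand an archive into its member files
#'
#' ZIP, TAR and gzip payloads are expanded recursively up to `max_depth`
#' (nested archives beyond the limit are returned unexpanded, classified as
#' `archive`). Member names are prefixed by the archive path. Expansion
#' aborts with a `suppbioc_archive_bomb` error once the cumulative expanded
#' size passes `ceiling_bytes` (default 1 GiB, mirroring the pipeline's
#' database-import cutoff for files over 1 GB).
#'
#' @param file an [sm_file()] with `media_class = "archive"` (or a raw
#'   payload, in which case `article_id`/`filename` label the members).
#' @param max_depth recursion depth; `1` expands only the outer archive.
#' @param ceiling_bytes total-expansion guard.
#' @param article_id,filename labels used when `file` is a raw payload.
#' @return List of [sm_file()] objects (never includes the archive itself).
#' @export
expand_archive <- function(file, max_depth = 3, ceiling_bytes = 2^30,
                           article_id = "NA", filename = "archive") {
  if (is.raw(file)) file <- sm_file(article_id, filename, file)
  stopifnot(inherits(file, "sm_file"), max_depth >= 1)
  budget <- new.env(parent = emptyenv())
  budget$left <- ceiling_bytes
  expand_archive_rec(file, as.integer(max_depth), budget)
}

expand_archive_rec <- function(file, depth, budget) {
  members <- archive_members(file)
  out <- list()
  for (m in members) {
    budget$left <- budget$left - m$size_bytes
    if (budget$left < 0)
      stop(errorCondition(
        paste0("archive expansion exceeded the total-bytes ceiling at ",
               m$filename),
        class = c("suppbioc_archive_bomb", "error")))
    if (m$media_class == "archive" && depth > 1L) {
      out <- c(out, expand_archive_rec(m, depth - 1L, budget))
    } else {
      out <- c(out, list(m))
    }
  }
  out
}

archive_members <- function(file) {
  p <- file$payload
  prefix <- paste0(file$filename, "/")
  if (is_zip_payload(p)) {
    raws <- tryCatch(
      withCallingHandlers(zip_members(p),
                          warning = function(w) stop(conditionMessage(w))),
      error = function(e)
        conversion_error(paste0("corrupt ZIP archive: ",
                                conditionMessage(e))))
    return(lapply(names(raws), function(nm)
      sm_file(file$article_id, paste0(prefix, nm), raws[[nm]])))
  }
  if (is_gzip_payload(p)) {
    inner <- tryCatch(memDecompress(p, type = "gzip"),
                      error = function(e)
                        conversion_error(paste0("corrupt gzip payload: ",
                                                conditionMessage(e))))
    nm <- sub("\\.t?gz$", "", basename(file$filename))
    if (identical(nm, basename(file$filename))) nm <- paste0(nm, ".out")
    if (grepl("\\.tgz$", basename(file$filename))) nm <- paste0(nm, ".tar")
    return(list(sm_file(file$article_id, paste0(prefix, nm), inner)))
  }
  # fall back to TAR
  tmp <- tempfile(fileext = ".tar")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(p, tmp)
  ex <- tempfile("tarx")
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  res <- tryCatch(
    withCallingHandlers(utils::untar(tmp, exdir = ex, tar = "internal"),
                        warning = function(w) stop(conditionMessage(w))),
    error = function(e)
      conversion_error(paste0("unrecognized or corrupt archive: ",
                              conditionMessage(e))))
  files <- list.files(ex, recursive = TRUE, full.names = FALSE)
  if (length(files) == 0)
    conversion_error("unrecognized or empty archive")
  lapply(files, function(nm) {
    f <- file.path(ex, nm)
    sm_file(file$article_id, paste0(prefix, nm),
            readBin(f, "raw", file.size(f)))
  })
}
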