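# Minimal local HTTP-style service over an index + converted corpus. The
# request handler is a pure function (easy to test); cmd_serve wraps it in a
# blocking base-R socket loop. All payloads are JSON / BioC-JSON.

#' Service state
#'
#' @param index a `retrieval_index`.
#' @param encoder encoder for query embeddings.
#' @param corpus optional [bioc_collection()] backing the fetch endpoint.
#' @return Object of class `suppbioc_service`.
#' @export
service_state <- function(index, encoder, corpus = NULL) {
  stopifnot(inherits(index, "retrieval_index"))
  structure(list(index = index, encoder = encoder, corpus = corpus),
            class = "suppbioc_service")
}

json_response <- function(status, payload) {
  list(status = status, content_type = "application/json",
       body = as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

#' Handle one service request
#'
#' Routes:
#' \describe{
#'   \item{`GET /search?q=&code=&top=`}{query-mode retrieval}
#'   \item{`GET /neighbors?article=&file=&top=`}{table-mode retrieval}
#'   \item{`GET /fetch?ids=a,b,c`}{BioC fetch; at most 50 ids, oversized
#'     responses flagged `attachment`}
#' }
#' Errors come back as `{"error": ...}` with an HTTP-style status code
#' (400 for bad requests, 404 for unknown resources).
#'
#' @param state a [service_state()].
#' @param method HTTP method (only GET is served).
#' @param path route path.
#' @param params named list of query parameters.
#' @return List with `status`, `content_type`, `body`.
#' @export
handle_request <- function(state, method, path, params = list()) {
  stopifnot(inherits(state, "suppbioc_service"))
  if (!identical(method, "GET"))
    return(json_response(405L, list(error = "only GET is supported")))
  tryCatch({
    if (path == "/search") {
      if (is.null(params$q) || is.null(params$code))
        return(json_response(400L, list(error = "q and code are required")))
      top <- as.integer(params$top %||% 10L)
      res <- search_by_query(state$index, state$encoder, params$q,
                             params$code, top_n = top)
      json_response(200L, list(results = res))
    } else if (path == "/neighbors") {
      if (is.null(params$article) || is.null(params$file))
        return(json_response(400L,
                             list(error = "article and file are required")))
      res <- search_by_table(state$index, params$article, params$file,
                             n_max = as.integer(params$top %||% 1000L))
      out <- cbind(parse_entry_key(res$key), similarity = res$similarity)
      json_response(200L, list(results = out))
    } else if (path == "/fetch") {
      if (is.null(params$ids))
        return(json_response(400L, list(error = "ids is required")))
      if (is.null(state$corpus))
        return(json_response(404L, list(error = "no corpus attached")))
      ids <- strsplit(params$ids, ",", fixed = TRUE)[[1]]
      res <- fetch_sm(state$corpus, ids)
      payload <- lapply(res, function(r) {
        if (!r$found) list(found = FALSE)
        else list(found = TRUE, attachment = r$attachment,
                  size_bytes = r$size_bytes,
                  collection = jsonlite::fromJSON(r$body,
                                                  simplifyVector = FALSE))
      })
      json_response(200L, payload)
    } else {
      json_response(404L, list(error = paste0("unknown route ", path)))
    }
  },
  suppbioc_bad_request = function(e)
    json_response(400L, list(error = conditionMessage(e))),
  suppbioc_not_found = function(e)
    json_response(404L, list(error = conditionMessage(e))),
  error = function(e)
    json_response(400L, list(error = conditionMessage(e))))
}

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p)
    utils::URLdecode(if (length(p) > 1) paste(p[-1], collapse = "=") else ""))
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

#' Serve the index over a local socket
#'
#' A deliberately small blocking HTTP/1.0 loop for local use (no TLS, no
#' auth, one request per connection); `max_requests` exists so tests can run
#' a bounded server.
#'
#' @param state a [service_state()].
#' @param port TCP port.
#' @param max_requests stop after this many requests (default unlimited).
#' @return Invisibly, the number of requests served.
#' @export
serve_loop <- function(state, port = 8080L, max_requests = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  log_msg("serving on port ", port)
  n <- 0
  while (n < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    req <- readLines(con, n = 1, warn = FALSE)
    m <- regmatches(req, regexec("^([A-Z]+) ([^? ]+)(\\?([^ ]*))? HTTP",
                                 req))[[1]]
    resp <- if (length(m) == 0)
      json_response(400L, list(error = "malformed request line"))
    else handle_request(state, m[2], m[3], parse_query_string(m[5]))
    writeLines(c(sprintf("HTTP/1.0 %d OK", resp$status),
                 paste0("Content-Type: ", resp$content_type),
                 "Connection: close", "", resp$body), con, sep = "\r\n")
    close(con)
    n <- n + 1
  }
  invisible(n)
}

#' Load a persisted index (and optional corpus) and serve it
#'
#' @param index_file index path.
#' @param port TCP port.
#' @param corpus_json optional BioC-JSON corpus path for the fetch endpoint.
#' @param config configuration list.
#' @param max_requests bound for testing.
#' @return Invisibly, the number of requests served.
#' @export
cmd_serve <- function(index_file, port = 8080L, corpus_json = NULL,
                      config = default_config(), max_requests = Inf) {
  idx <- read_index(index_file)
  corpus <- if (!is.null(corpus_json))
    read_bioc_json(paste(readLines(corpus_json, warn = FALSE),
                         collapse = "\n"))
  state <- service_state(idx, get_encoder(config$encoder), corpus)
  serve_loop(state, port = port, max_requests = max_requests)
}
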