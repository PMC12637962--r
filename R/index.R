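# The searchable index over categorized table embeddings: exact cosine
# ranking only (no approximate shortcuts), deterministic ordering, pre-ranked
# neighbour lists for table-to-table search.

entry_key <- function(article_id, filename, table_id) {
  paste(article_id, filename, table_id, sep = "\x1f")
}

#' Build the retrieval index from a converted corpus
#'
#' One entry per table passage: the table is linearized, encoded, and
#' assigned a category code by 1-NN against the categorized seed set.
#' Entries are ordered deterministically by (article_id, filename, table_id).
#'
#' @param corpus a [bioc_collection()] (or list of documents).
#' @param encoder a `suppbioc_encoder`.
#' @param categorized a [categorized_tables()] seed set.
#' @param tau "Other" threshold passed to [assign_category()].
#' @param max_chars linearization cap per table.
#' @return Object of class `retrieval_index`: `entries` (data.frame with
#'   `article_id`, `filename`, `table_id`, `code`, `similarity`, `n_rows`,
#'   `n_cols`), `vectors` (matrix), `neighbors` (`NULL` until
#'   [precompute_neighbors()]), `version`.
#' @export
build_index <- function(corpus, encoder, categorized, tau = 0.30,
                        max_chars = 2000L) {
  if (!inherits(corpus, "bioc_collection")) corpus <- bioc_collection(corpus)
  stopifnot(inherits(encoder, "suppbioc_encoder"),
            inherits(categorized, "categorized_set"))
  if (ncol(categorized$vectors) != encoder$d)
    stop("encoder dimension (", encoder$d, ") does not match the cluster ",
         "model / categorized set dimension (", ncol(categorized$vectors), ")")
  rows <- list(); vecs <- list()
  for (d in corpus$documents) {
    parts <- regmatches(d$doc_id, regexpr("/", d$doc_id), invert = TRUE)[[1]]
    art <- parts[1]; fname <- if (length(parts) > 1) parts[2] else ""
    for (tab in document_tables(d)) {
      v <- encode(encoder, linearize_table(tab, max_chars))
      rows[[length(rows) + 1L]] <- data.frame(
        article_id = art, filename = fname, table_id = tab$table_id,
        n_rows = tab$n_rows, n_cols = tab$n_cols, stringsAsFactors = FALSE)
      vecs[[length(vecs) + 1L]] <- v
    }
  }
  if (length(rows) == 0) {
    entries <- data.frame(article_id = character(0), filename = character(0),
                          table_id = character(0), code = character(0),
                          similarity = numeric(0), n_rows = integer(0),
                          n_cols = integer(0), stringsAsFactors = FALSE)
    return(structure(list(entries = entries,
                          vectors = matrix(0, 0, encoder$d),
                          neighbors = NULL, encoder = encoder$name,
                          version = INDEX_FORMAT_VERSION),
                     class = "retrieval_index"))
  }
  entries <- do.call(rbind, rows)
  vectors <- do.call(rbind, vecs)
  ord <- order(entries$article_id, entries$filename, entries$table_id,
               method = "radix")
  entries <- entries[ord, , drop = FALSE]
  vectors <- vectors[ord, , drop = FALSE]
  asg <- assign_category(vectors, categorized, tau = tau)
  entries$code <- asg$code
  entries$similarity <- asg$similarity
  rownames(entries) <- NULL
  structure(list(entries = entries, vectors = vectors, neighbors = NULL,
                 encoder = encoder$name, version = INDEX_FORMAT_VERSION),
            class = "retrieval_index")
}

INDEX_FORMAT_VERSION <- "suppbioc-index-v1"

#' @export
print.retrieval_index <- function(x, ...) {
  cat("<retrieval_index> ", nrow(x$entries), " table(s), d = ",
      ncol(x$vectors), if (!is.null(x$neighbors)) ", neighbors precomputed",
      "\n", sep = "")
  invisible(x)
}

index_keys <- function(index) {
  with(index$entries, entry_key(article_id, filename, table_id))
}

cosine_matrix <- function(a, b) {
  na <- sqrt(rowSums(a^2)); na[na == 0] <- Inf
  nb <- sqrt(rowSums(b^2)); nb[nb == 0] <- Inf
  (a / na) %*% t(b / nb)
}

#' Pre-rank the nearest neighbours of every index entry
#'
#' Exact top-`min(N, n - 1)` by cosine for each entry (self excluded), ties
#' broken by entry key — the stored "top 1,000 matches" that make
#' table-to-table search instant.
#'
#' @param index a [build_index()] result.
#' @param N neighbour-list length cap (default 1000).
#' @return The index with `neighbors` filled: per entry a data.frame with
#'   `key` and `similarity`, similarity non-increasing.
#' @export
precompute_neighbors <- function(index, N = 1000L) {
  stopifnot(inherits(index, "retrieval_index"))
  n <- nrow(index$entries)
  if (n == 0) stop("index non-empty required")
  keys <- index_keys(index)
  sims <- cosine_matrix(index$vectors, index$vectors)
  index$neighbors <- lapply(seq_len(n), function(i) {
    s <- sims[i, -i]
    k <- keys[-i]
    ord <- order(-s, k, method = "radix")
    take <- ord[seq_len(min(N, n - 1L))]
    data.frame(key = k[take], similarity = s[take], stringsAsFactors = FALSE)
  })
  names(index$neighbors) <- keys
  index
}

#' All valid category codes
#'
#' The registry's codes plus the reserved `OTHR` fallback.
#'
#' @param registry label -> code map (see [load_code_registry()]).
#' @return Character vector of codes.
#' @export
registry_codes <- function(registry = load_code_registry()) {
  c(unname(registry), OTHER_CODE)
}

#' Query-mode search: free text plus a category code
#'
#' Entries are filtered to the requested code, each article is scored by the
#' maximum cosine similarity between the query embedding and its filtered
#' tables, and the `top_n` articles are returned in descending score order
#' (ties by article id).
#'
#' @param index a [retrieval_index].
#' @param encoder encoder used for the query (same space as the index).
#' @param query_text free-text query.
#' @param code category code (see [load_code_registry()]).
#' @param top_n number of articles to return.
#' @param registry code registry used for validation.
#' @return data.frame with `article_id`, `best_table` (entry key), `score`.
#' @export
search_by_query <- function(index, encoder, query_text, code, top_n = 10L,
                            registry = load_code_registry()) {
  stopifnot(inherits(index, "retrieval_index"), top_n >= 1)
  # registry codes plus any generated (non-registry) codes the index carries
  valid <- union(registry_codes(registry), unique(index$entries$code))
  if (!code %in% valid)
    stop("unknown category code '", code, "'; valid codes: ",
         paste(valid, collapse = ", "))
  sel <- which(index$entries$code == code)
  if (length(sel) == 0)
    return(data.frame(article_id = character(0), best_table = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  q <- encode(encoder, query_text)
  sims <- as.vector(cosine_matrix(matrix(q, 1), index$vectors[sel, ,
                                                              drop = FALSE]))
  keys <- index_keys(index)[sel]
  art <- index$entries$article_id[sel]
  ord <- order(-sims, keys, method = "radix")
  art_o <- art[ord]
  first <- !duplicated(art_o)   # per article, its best-scoring table
  res <- data.frame(article_id = art_o[first],
                    best_table = keys[ord][first],
                    score = sims[ord][first], stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$article_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Table-mode search: most similar tables to a known file's tables
#'
#' The union of the file's tables' neighbour lists, deduplicated by entry
#' key keeping the maximum similarity, re-sorted, and truncated to `n_max`.
#'
#' @param index a [retrieval_index] (neighbour lists are computed on demand
#'   when absent).
#' @param article_id,filename the file whose tables anchor the search.
#' @param n_max result cap (default 1000).
#' @return data.frame with `key` and `similarity`, descending.
#' @export
search_by_table <- function(index, article_id, filename, n_max = 1000L) {
  stopifnot(inherits(index, "retrieval_index"))
  sel <- index$entries$article_id == article_id &
    index$entries$filename == filename
  if (!any(sel))
    stop(errorCondition(
      paste0("no indexed tables for ", article_id, "/", filename),
      class = c("suppbioc_not_found", "error")))
  if (is.null(index$neighbors)) index <- precompute_neighbors(index, n_max)
  keys <- index_keys(index)
  own <- keys[sel]
  nb <- do.call(rbind, index$neighbors[own])
  if (nrow(nb) == 0)
    return(data.frame(key = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  nb <- nb[order(-nb$similarity, nb$key, method = "radix"), , drop = FALSE]
  nb <- nb[!duplicated(nb$key), , drop = FALSE]
  rownames(nb) <- NULL
  utils::head(nb, n_max)
}

#' Split an entry key back into its components
#'
#' @param key entry key (as produced internally and in neighbour lists).
#' @return data.frame with `article_id`, `filename`, `table_id`.
#' @export
parse_entry_key <- function(key) {
  parts <- strsplit(key, "\x1f", fixed = TRUE)
  data.frame(article_id = vapply(parts, `[`, "", 1),
             filename = vapply(parts, `[`, "", 2),
             table_id = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

#' Persist / load an index as a single versioned JSON file
#'
#' @param index a [retrieval_index].
#' @param path file path.
#' @return `write_index`: the path, invisibly. `read_index`: the index.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "retrieval_index"))
  payload <- list(version = index$version, encoder = index$encoder,
                  d = ncol(index$vectors),
                  entries = index$entries,
                  vectors = apply(index$vectors, 1, identity,
                                  simplify = FALSE),
                  neighbors = index$neighbors)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(x$version, INDEX_FORMAT_VERSION))
    stop("unsupported index format version: ", x$version)
  vectors <- if (is.matrix(x$vectors)) x$vectors
             else if (length(x$vectors) > 0) do.call(rbind, x$vectors)
             else matrix(0, 0, x$d)
  nb <- x$neighbors
  if (!is.null(nb)) nb <- lapply(nb, as.data.frame)
  structure(list(entries = as.data.frame(x$entries), vectors = vectors,
                 neighbors = nb, encoder = x$encoder, version = x$version),
            class = "retrieval_index")
}
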