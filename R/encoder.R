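# Pluggable text encoders and cosine geometry.
#
# Retrieval quality in production hinges on a biomedical sentence encoder
# producing 768-dimensional vectors; that model is configuration-selected and
# optional. The built-in "hash" encoder is a deterministic signed
# bag-of-tokens feature hasher: it needs no downloads, is stable across
# sessions, and gives near-orthogonal vectors for disjoint vocabularies,
# which is what the clustering/retrieval tests rely on.

#' Construct a deterministic hashing text encoder
#'
#' Tokenizes on non-alphanumeric characters, lowercases, hashes every token
#' into one of `d` buckets with a +/-1 sign, and L2-normalizes the result.
#' Same text, same vector — in-session and across sessions.
#'
#' @param d embedding dimension (default 768, the production encoder's width).
#' @return Object of class `suppbioc_encoder`.
#' @export
hash_encoder <- function(d = 768L) {
  d <- as.integer(d)
  stopifnot(d >= 2L)
  structure(list(name = sprintf("hash-%d", d), d = d), class = "suppbioc_encoder")
}

#' @export
print.suppbioc_encoder <- function(x, ...) {
  cat("<suppbioc_encoder> ", x$name, " (d = ", x$d, ")\n", sep = "")
  invisible(x)
}

# 32-bit polynomial rolling hash (base 31), exact in doubles
token_hash <- function(token) {
  b <- utf8ToInt(token)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 4294967296
  h
}

tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Encode text into an embedding vector
#'
#' @param encoder an encoder (see [hash_encoder()], [get_encoder()]).
#' @param text character scalar. Text that is empty after whitespace
#'   normalization encodes to the zero vector by convention.
#' @return Numeric vector of length `encoder$d` (unit norm unless zero).
#' @examples
#' enc <- hash_encoder(64)
#' sum(encode(enc, "gene expression") * encode(enc, "expression gene"))
#' @export
encode <- function(encoder, text) {
  stopifnot(inherits(encoder, "suppbioc_encoder"), is.character(text),
            length(text) == 1)
  v <- numeric(encoder$d)
  toks <- tokenize(text)
  if (length(toks) == 0) return(v)
  for (tk in toks) {
    h <- token_hash(tk)
    bucket <- (h %% encoder$d) + 1
    sign <- 1 - 2 * ((h %/% encoder$d) %% 2)
    v[bucket] <- v[bucket] + sign
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Cosine similarity
#'
#' `dot(u, v) / (|u||v|)`; returns 0 if either vector has zero norm (keeps
#' ranking total when empty-text zero vectors are present).
#'
#' @param u,v numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Linearize a table for encoding
#'
#' Caption (if any), then the row-major cells joined with single spaces
#' within a row and `" | "` between rows. Truncation happens only at cell
#' boundaries, so the output never cuts a cell value in half.
#'
#' @param tab an [sm_table()].
#' @param max_chars maximum output length (default unlimited).
#' @return Character scalar.
#' @examples
#' linearize_table(sm_table(c("g1", "g2"), 2, 1, "t", caption = "Top hits"))
#' @export
linearize_table <- function(tab, max_chars = Inf) {
  validate_sm_table(tab)
  pieces <- character(0)
  seps <- character(0)
  if (!is.null(tab$caption)) { pieces <- tab$caption; seps <- "" }
  if (tab$n_rows > 0) {
    rows <- rep(seq_len(tab$n_rows), each = tab$n_cols)
    firsts <- rep(c(TRUE, rep(FALSE, tab$n_cols - 1L)), tab$n_rows)
    cellsep <- ifelse(firsts, " | ", " ")
    if (length(pieces) == 0) cellsep[1] <- "" else cellsep[1] <- " "
    # within the first row the leading cell joins with a space after caption;
    # subsequent rows open with " | "
    pieces <- c(pieces, tab$cells)
    seps <- c(seps, cellsep)
  }
  out <- ""
  for (i in seq_along(pieces)) {
    nxt <- paste0(if (nzchar(out)) seps[i] else "", pieces[i])
    if (nchar(out) + nchar(nxt) > max_chars) break
    out <- paste0(out, nxt)
  }
  out
}

#' Look up an encoder by registry name
#'
#' The built-in registry knows `"hash-<d>"` (e.g. `"hash-768"`). External
#' encoders (such as a biomedical transformer served out-of-process) can be
#' plugged in by registering a constructor.
#'
#' @param name registry name.
#' @return A `suppbioc_encoder`.
#' @export
get_encoder <- function(name) {
  if (grepl("^hash-[0-9]+$", name))
    return(hash_encoder(as.integer(sub("^hash-", "", name))))
  ctor <- encoder_registry_env$constructors[[name]]
  if (is.null(ctor))
    stop("unknown encoder '", name, "'; known: hash-<d>",
         if (length(encoder_registry_env$constructors) > 0)
           paste0(", ", paste(names(encoder_registry_env$constructors),
                              collapse = ", ")))
  ctor()
}

encoder_registry_env <- new.env(parent = emptyenv())
encoder_registry_env$constructors <- list()

#' Register an external encoder constructor
#'
#' @param name registry name.
#' @param constructor zero-argument function returning a `suppbioc_encoder`.
#' @return Invisibly, `name`.
#' @export
register_encoder <- function(name, constructor) {
  stopifnot(is.function(constructor))
  encoder_registry_env$constructors[[name]] <- constructor
  invisible(name)
}
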