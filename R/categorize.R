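# Table categorization: cluster a labeled seed set of table embeddings,
# name each cluster by its most frequent label, give it a short registry
# code, and assign any new table the code of its most cosine-similar
# categorized table (with an "Other" fallback below a similarity threshold).

OTHER_CODE <- "OTHR"

#' Labeled seed set of table embeddings
#'
#' @param table_ids character vector of unique table identifiers.
#' @param vectors numeric matrix of embeddings, one row per table.
#' @param labels free-text category label per table (non-empty).
#' @return Object of class `labeled_table_set` with a label-frequency
#'   `counts` table.
#' @export
labeled_table_set <- function(table_ids, vectors, labels) {
  vectors <- as.matrix(vectors)
  stopifnot(length(table_ids) == nrow(vectors),
            length(labels) == nrow(vectors))
  if (anyDuplicated(table_ids)) stop("duplicate table_ids in labeled set")
  if (any(!nzchar(labels))) stop("labels must be non-empty")
  structure(list(table_ids = as.character(table_ids), vectors = vectors,
                 labels = as.character(labels),
                 counts = table(labels)),
            class = "labeled_table_set")
}

#' @export
print.labeled_table_set <- function(x, ...) {
  cat("<labeled_table_set> ", length(x$table_ids), " tables, ",
      length(x$counts), " distinct labels, d = ", ncol(x$vectors), "\n",
      sep = "")
  invisible(x)
}

#' Load the category-code registry
#'
#' A two-column TSV (`code`, `label`). The package ships the 14 codes used
#' for type-filtered retrieval (e.g. GPED = Gene Expression Data).
#'
#' @param path registry file; default is the shipped registry.
#' @return Named character vector: label -> code.
#' @export
load_code_registry <- function(path = system.file("extdata",
                                                  "category_codes.tsv",
                                                  package = "suppbioc")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "label") %in% names(df)))
  stats::setNames(df$code, df$label)
}

#' Derive a short code for a category label
#'
#' Registry labels use their registered code; otherwise the first four
#' consonant-preferring uppercase letters of the label, with digit suffixing
#' on collision. The reserved code `OTHR` is never produced.
#'
#' @param label free-text label.
#' @param existing codes already taken.
#' @param registry label -> code map (see [load_code_registry()]).
#' @return 2-4 character uppercase code.
#' @export
label_code <- function(label, existing = character(0),
                       registry = load_code_registry()) {
  code <- if (label %in% names(registry)) unname(registry[[label]]) else {
    letters_only <- strsplit(toupper(gsub("[^A-Za-z]", "", label)), "")[[1]]
    vowel <- letters_only %in% c("A", "E", "I", "O", "U")
    cand <- c(letters_only[!vowel], letters_only[vowel])
    code <- paste(cand[seq_len(min(4, length(cand)))], collapse = "")
    if (nchar(code) < 4)
      code <- paste0(code, strrep("X", 4 - nchar(code)))
    code
  }
  if (!code %in% c(existing, OTHER_CODE)) return(code)
  for (i in 2:99) {
    cand <- paste0(substr(code, 1, 3), i)
    if (!cand %in% c(existing, OTHER_CODE)) return(cand)
  }
  stop("could not derive a unique code for label '", label, "'")
}

#' Name clusters by their most frequent label
#'
#' The representative label of each cluster is the modal raw label among its
#' members, ties broken lexicographically; codes come from the registry for
#' known labels and from [label_code()] generation otherwise, unique across
#' clusters with `OTHR` reserved for the "Other" fallback.
#'
#' @param assignment integer cluster per labeled entry (1..k).
#' @param labels raw label per entry.
#' @param k number of clusters.
#' @param registry label -> code map.
#' @return List with `representative` and `code`, both length k.
#' @export
name_clusters <- function(assignment, labels, k = max(assignment),
                          registry = load_code_registry()) {
  representative <- character(k)
  code <- character(k)
  for (j in seq_len(k)) {
    lab <- labels[assignment == j]
    if (length(lab) == 0) stop("cluster ", j, " is empty")
    counts <- table(lab)
    top <- names(counts)[counts == max(counts)]
    representative[j] <- sort(top, method = "radix")[1]
    code[j] <- label_code(representative[j], existing = code[seq_len(j - 1L)],
                          registry = registry)
  }
  list(representative = representative, code = code)
}

#' Fit the category cluster model over a labeled seed set
#'
#' In the default frequency-weighted mode, each distinct label contributes
#' one point (the mean of its tables' embeddings) weighted by its count —
#' clustering the categories "based on their count and the semantic
#' similarity". In unweighted mode every table embedding is a point. When
#' `k` is `NULL` the cluster count is chosen by [k_selection_report()] over
#' `k_grid` (elbow + gap + silhouette vote).
#'
#' @param lset a [labeled_table_set()].
#' @param k fixed cluster count, or `NULL` to select over `k_grid`.
#' @param k_grid candidate cluster counts (used when `k` is `NULL`).
#' @param seed integer seed for every stochastic step.
#' @param tau "Other" similarity threshold in `[0, 1]`; assignments whose
#'   best similarity falls below `tau` get code `OTHR`.
#' @param weighted frequency-weighted (label-level) or plain (table-level)
#'   clustering.
#' @param B,n_init passed to the k-selection machinery.
#' @param registry label -> code map.
#' @return Object of class `cluster_model`: `k`, `centroids`, `assignment`
#'   (named by table_id), `representative`, `code`, `tau`, `seed`, and the
#'   `selection` report when k was selected.
#' @export
fit_cluster_model <- function(lset, k = NULL, k_grid = NULL, seed = 1L,
                              tau = 0.30, weighted = TRUE, B = 20L,
                              n_init = 5L, registry = load_code_registry()) {
  stopifnot(inherits(lset, "labeled_table_set"), tau >= 0, tau <= 1)
  if (weighted) {
    labs <- sort(unique(lset$labels), method = "radix")
    pts <- t(vapply(labs, function(l)
      colMeans(lset$vectors[lset$labels == l, , drop = FALSE]),
      numeric(ncol(lset$vectors))))
    wts <- as.numeric(lset$counts[labs])
  } else {
    pts <- lset$vectors
    wts <- NULL
  }
  selection <- NULL
  if (is.null(k)) {
    if (is.null(k_grid)) k_grid <- seq_len(min(10L, nrow(pts)))
    selection <- k_selection_report(pts, k_grid, B = B, seed = seed,
                                    n_init = n_init, weights = wts)
    k <- selection$chosen_k
  }
  fit <- kmeans_fit(pts, k, seed = seed, n_init = max(n_init, 10L),
                    weights = wts)
  if (weighted) {
    # map each table to its label's cluster
    assignment <- fit$assignment[match(lset$labels, labs)]
  } else {
    assignment <- fit$assignment
  }
  names(assignment) <- lset$table_ids
  nm <- name_clusters(assignment, lset$labels, k = k, registry = registry)
  structure(list(k = as.integer(k), centroids = fit$centroids,
                 assignment = assignment,
                 representative = nm$representative, code = nm$code,
                 tau = tau, seed = as.integer(seed), selection = selection),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", x$k, ", tau = ", x$tau, "\n", sep = "")
  for (j in seq_len(x$k))
    cat(sprintf("  %-4s %s (%d tables)\n", x$code[j], x$representative[j],
                sum(x$assignment == j)))
  invisible(x)
}

#' Attach per-table category codes to a labeled set
#'
#' @param model a [cluster_model()].
#' @param lset the [labeled_table_set()] the model was fitted on (or any set
#'   whose table ids appear in the model's assignment).
#' @return Object of class `categorized_set`: `table_ids`, `vectors`,
#'   `codes`.
#' @export
categorized_tables <- function(model, lset) {
  idx <- model$assignment[lset$table_ids]
  if (anyNA(idx)) stop("labeled set contains tables unknown to the model")
  structure(list(table_ids = lset$table_ids, vectors = lset$vectors,
                 codes = model$code[idx]),
            class = "categorized_set")
}

#' Assign a category by nearest categorized table
#'
#' 1-nearest-neighbour by cosine over all categorized tables; if the best
#' similarity is below `tau` the reserved code `OTHR` is returned (with the
#' best similarity still reported). Exact ties go to the smaller table id.
#' `mode = "centroid"` compares against cluster centroids instead (the
#' alternative reading of the pipeline description); centroids then require
#' a `cluster_model` via `model`.
#'
#' @param v embedding vector (or a matrix of query vectors in rows).
#' @param categorized a [categorized_tables()] set (table mode).
#' @param tau "Other" threshold in `[0, 1]`.
#' @param mode `"table"` (default, 1-NN over categorized tables) or
#'   `"centroid"`.
#' @param model a [fit_cluster_model()] result, needed for centroid mode.
#' @return For a single vector, list `(code, similarity)`; for a matrix, a
#'   data.frame with columns `code`, `similarity`.
#' @export
assign_category <- function(v, categorized = NULL, tau = 0.30,
                            mode = c("table", "centroid"), model = NULL) {
  mode <- match.arg(mode)
  if (mode == "table") {
    stopifnot(inherits(categorized, "categorized_set"))
    ref <- categorized$vectors
    codes <- categorized$codes
    keys <- categorized$table_ids
  } else {
    stopifnot(inherits(model, "cluster_model"))
    ref <- model$centroids
    codes <- model$code
    keys <- sprintf("cluster%03d", seq_len(nrow(ref)))
  }
  if (nrow(ref) == 0) stop("empty categorized set")
  single <- is.null(dim(v))
  q <- if (single) matrix(v, 1) else as.matrix(v)
  if (ncol(q) != ncol(ref))
    stop("dimension mismatch: query d = ", ncol(q), ", index d = ", ncol(ref))
  rn <- sqrt(rowSums(ref^2)); rn[rn == 0] <- Inf
  qn <- sqrt(rowSums(q^2)); qn[qn == 0] <- Inf
  sims <- (q / qn) %*% t(ref / rn)   # n_query x n_ref cosine matrix
  ord <- order(keys, method = "radix")
  out <- lapply(seq_len(nrow(q)), function(i) {
    s <- sims[i, ]
    best <- max(s)
    # ties by smaller table_id
    j <- ord[which(s[ord] == best)[1]]
    list(code = if (best < tau) OTHER_CODE else codes[j], similarity = best)
  })
  if (single) return(out[[1]])
  data.frame(code = vapply(out, `[[`, "", "code"),
             similarity = vapply(out, `[[`, 0, "similarity"),
             stringsAsFactors = FALSE)
}

#' Calibrate the "Other" threshold from a target Other-fraction
#'
#' Given best-neighbour similarities of a calibration set, returns the tau
#' for which approximately `target` of the calibration tables fall below the
#' threshold. The realized Other-fraction is non-decreasing in tau by
#' construction.
#'
#' @param best_sims numeric vector of best similarities.
#' @param target desired Other-fraction in `[0, 1]`.
#' @return tau in `[0, 1]`.
#' @export
calibrate_tau <- function(best_sims, target) {
  stopifnot(target >= 0, target <= 1, length(best_sims) > 0)
  unname(stats::quantile(best_sims, probs = target, type = 1))
}
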