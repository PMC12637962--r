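# Seeded synthetic supplementary-material corpora with full ground truth.
# This is what makes the whole pipeline testable offline: it stands in for a
# PMC-style corpus with known media classes, known grids, known category
# labels, and a known number of deliberately corrupted files.

#' Specification of a synthetic corpus
#'
#' Category vocabularies are pairwise disjoint by default (clean
#' separability); `overlap` shares a fraction of tokens across categories for
#' stress testing. Corrupted files are generated in container formats
#' (spreadsheet / word-processor / PDF / archive) and truncated at a random
#' byte, which reliably breaks them.
#'
#' @param n_articles number of articles.
#' @param n_categories number of table categories (each with its own
#'   vocabulary of at least 50 tokens).
#' @param categories optional list of `list(label=, vocabulary=)` overriding
#'   the generated ones.
#' @param files_per_article integer vector the per-article file count is
#'   drawn from.
#' @param failure_rate fraction of files planted as corrupted (exactly
#'   `round(rate * n_files)` files).
#' @param archive_rate fraction of files emitted as ZIP archives of CSVs.
#' @param mean_rows,mean_cols mean table shape.
#' @param overlap fraction of each category vocabulary shared across all
#'   categories (0 = disjoint).
#' @param seed integer seed; the generated tree is byte-identical for a
#'   fixed spec.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 50L, n_categories = 5L,
                        categories = NULL, files_per_article = 1:3,
                        failure_rate = 0.05, archive_rate = 0.10,
                        mean_rows = 8, mean_cols = 4, overlap = 0,
                        seed = 1L) {
  stopifnot(failure_rate >= 0, failure_rate <= 1,
            archive_rate >= 0, archive_rate <= 1,
            overlap >= 0, overlap < 1)
  if (is.null(categories)) {
    shared <- sprintf("common%03d", 1:50)
    categories <- lapply(seq_len(n_categories), function(ci) {
      vocab <- sprintf("cat%02dtok%03d", ci, 1:60)
      if (overlap > 0) {
        n_shared <- round(overlap * length(vocab))
        vocab[seq_len(n_shared)] <- shared[seq_len(n_shared)]
      }
      list(label = sprintf("Synthetic Category %02d", ci), vocabulary = vocab)
    })
  }
  vocabs <- lapply(categories, `[[`, "vocabulary")
  stopifnot(all(lengths(vocabs) >= 50))
  if (overlap == 0 && length(vocabs) > 1) {
    all_tok <- unlist(vocabs)
    if (anyDuplicated(all_tok))
      stop("category vocabularies must be pairwise disjoint")
  }
  structure(list(n_articles = as.integer(n_articles),
                 categories = categories,
                 files_per_article = as.integer(files_per_article),
                 failure_rate = failure_rate, archive_rate = archive_rate,
                 mean_rows = mean_rows, mean_cols = mean_cols,
                 overlap = overlap, seed = as.integer(seed)),
            class = "corpus_spec")
}

# sample() treats a length-1 numeric as 1:x; this does not
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1)

rand_grid <- function(vocab, mean_rows, mean_cols) {
  nr <- max(2L, stats::rpois(1, mean_rows))
  nc <- max(2L, stats::rpois(1, mean_cols))
  matrix(sample(vocab, nr * nc, replace = TRUE), nr, nc)
}

grid_csv <- function(m, delim) {
  paste(apply(m, 1, paste, collapse = delim), collapse = "\n")
}

#' Generate a synthetic corpus on disk
#'
#' Emits, per the spec's rates: CSV/TSV files, minimal OOXML spreadsheets and
#' word-processor documents, tab-delimited plain text, single-page text PDFs,
#' and ZIP archives of CSVs, under `dir/<article_id>/<filename>`. Cell
#' content is drawn from the article's category vocabulary. Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [corpus_spec()].
#' @param dir target directory (created; must be writable).
#' @return Object of class `corpus_ground_truth`: `files` (one record per
#'   generated file, archive members included), `labels` (article ->
#'   category label), `expected` (conversion accounting: `n_total`
#'   conversion attempts, `n_failed` planted failures, `n_skipped`), `dir`.
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create corpus directory ", dir)
  files <- list()
  labels <- character(0)
  local_seed(spec$seed, {
    arts <- sprintf("PMC%07d", seq_len(spec$n_articles))
    cat_of <- sample(length(spec$categories), spec$n_articles, replace = TRUE)
    plan <- list()
    for (ai in seq_along(arts)) {
      nf <- sample1(spec$files_per_article)
      for (fi in seq_len(nf)) {
        kind <- if (stats::runif(1) < spec$archive_rate) "archive"
        else sample(c("csv", "tsv", "xlsx", "docx", "txt", "pdf"), 1,
                    prob = c(0.25, 0.15, 0.2, 0.15, 0.1, 0.15))
        plan[[length(plan) + 1L]] <- list(article = arts[ai],
                                          cat = cat_of[ai], i = fi,
                                          kind = kind)
      }
    }
    n_corrupt <- round(spec$failure_rate * length(plan))
    corrupt_idx <- if (n_corrupt > 0)
      sample(length(plan), n_corrupt) else integer(0)
    # corrupted files must be truncatable containers
    for (ci in corrupt_idx)
      plan[[ci]]$kind <- sample(c("xlsx", "docx", "pdf", "archive"), 1)
    for (pi in seq_along(plan)) {
      p <- plan[[pi]]
      cat_def <- spec$categories[[p$cat]]
      vocab <- cat_def$vocabulary
      corrupted <- pi %in% corrupt_idx
      recs <- generate_one_file(p, vocab, spec, corrupted, dir)
      files <- c(files, recs)
      labels[p$article] <- cat_def$label
    }
  })
  media <- vapply(files, `[[`, "", "media_class")
  in_arc <- vapply(files, `[[`, TRUE, "in_archive")
  corrupted <- vapply(files, `[[`, TRUE, "corrupted")
  # conversion attempts: every top-level non-archive file, every archive
  # member, plus each corrupted archive container (counted once, as failed)
  n_total <- sum(!in_arc & media != "archive") + sum(in_arc) +
    sum(corrupted & media == "archive")
  structure(list(files = files, labels = labels,
                 expected = list(n_total = n_total,
                                 n_failed = sum(corrupted),
                                 n_skipped = 0L),
                 spec = spec, dir = dir),
            class = "corpus_ground_truth")
}

generate_one_file <- function(p, vocab, spec, corrupted, dir) {
  art_dir <- file.path(dir, p$article)
  if (!dir.exists(art_dir)) dir.create(art_dir)
  mk_rec <- function(filename, media_class, grids, in_archive = FALSE,
                     paragraphs = NULL) {
    list(article_id = p$article, filename = filename,
         media_class = media_class, label = NULL, corrupted = corrupted,
         grids = grids, in_archive = in_archive, paragraphs = paragraphs,
         category = NULL)
  }
  recs <- list()
  kind <- p$kind
  fname <- sprintf("file%02d.%s", p$i,
                   ifelse(kind == "archive", "zip", kind))
  bytes <- NULL
  if (kind %in% c("csv", "tsv")) {
    m <- rand_grid(vocab, spec$mean_rows, spec$mean_cols)
    bytes <- charToRaw(grid_csv(m, if (kind == "csv") "," else "\t"))
    recs <- list(mk_rec(fname, "delimited_text", list(t1 = m)))
  } else if (kind == "txt") {
    m <- rand_grid(vocab, spec$mean_rows, spec$mean_cols)
    bytes <- charToRaw(grid_csv(m, "\t"))
    recs <- list(mk_rec(fname, "plain_text", list(t1 = m)))
  } else if (kind == "xlsx") {
    n_sheets <- sample(1:2, 1)
    sheets <- lapply(seq_len(n_sheets), function(si)
      rand_grid(vocab, spec$mean_rows, spec$mean_cols))
    names(sheets) <- sprintf("Sheet%d", seq_len(n_sheets))
    bytes <- write_xlsx_raw(sheets)
    grids <- stats::setNames(sheets, sprintf("sheet%d", seq_len(n_sheets)))
    recs <- list(mk_rec(fname, "spreadsheet", grids))
  } else if (kind == "docx") {
    paras <- vapply(seq_len(sample(1:3, 1)), function(i)
      paste(sample(vocab, 8, TRUE), collapse = " "), "")
    m <- rand_grid(vocab, spec$mean_rows, spec$mean_cols)
    truth <- m
    if (stats::runif(1) < 0.25 && ncol(m) >= 2) {
      # merged 2-column header cell; ground truth duplicates the value
      attr(m, "gridspan") <- data.frame(row = 1, col = 1, span = 2)
      truth[1, 2] <- truth[1, 1]
    }
    bytes <- write_docx_raw(c(as.list(paras), list(m)))
    recs <- list(mk_rec(fname, "word_processor", list(tbl1 = truth),
                        paragraphs = paras))
  } else if (kind == "pdf") {
    paras <- vapply(seq_len(sample(2:4, 1)), function(i)
      paste(sample(vocab, 10, TRUE), collapse = " "), "")
    bytes <- write_pdf_raw(paras)
    recs <- list(mk_rec(fname, "pdf", list(), paragraphs = paras))
  } else if (kind == "archive") {
    n_members <- sample(1:2, 1)
    members <- list()
    for (mi in seq_len(n_members)) {
      m <- rand_grid(vocab, spec$mean_rows, spec$mean_cols)
      mname <- sprintf("inner%02d.csv", mi)
      members[[mname]] <- charToRaw(grid_csv(m, ","))
      recs <- c(recs, list(mk_rec(paste0(fname, "/", mname),
                                  "delimited_text", list(t1 = m),
                                  in_archive = TRUE)))
    }
    bytes <- zip_build(members)
    recs <- c(list(mk_rec(fname, "archive", list())), recs)
  }
  if (corrupted) {
    cut <- sample(seq(10L, max(11L, floor(length(bytes) * 0.6))), 1)
    bytes <- bytes[seq_len(min(cut, length(bytes)))]
    # a truncated archive loses its members
    recs <- recs[!vapply(recs, `[[`, TRUE, "in_archive")]
    recs <- lapply(recs, function(r) { r$grids <- list(); r })
  }
  writeBin(bytes, file.path(dir, p$article, fname))
  lapply(recs, function(r) { r$category <- p$cat; r })
}

#' Load a corpus directory as sm_file objects
#'
#' @param dir a directory laid out as `<article_id>/<filename>`.
#' @return List of [sm_file()] objects sorted by (article, filename).
#' @export
load_corpus_dir <- function(dir) {
  arts <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  out <- list()
  for (a in arts) {
    for (f in sort(list.files(file.path(dir, a)))) {
      path <- file.path(dir, a, f)
      out <- c(out, list(sm_file(a, f, readBin(path, "raw",
                                               file.size(path)))))
    }
  }
  out
}

#' Stratified labeled seed set from ground truth
#'
#' Samples `fraction` of the ground-truth tables per category (at least one
#' per category or an error), encodes their grids, and returns the labeled
#' set used to fit the cluster model. Table ids are
#' `article/filename/table_id` keys.
#'
#' @param truth a [generate_corpus()] result.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param encoder encoder for the table embeddings.
#' @return A [labeled_table_set()].
#' @export
make_labeled_seed <- function(truth, fraction, seed = 1L,
                              encoder = hash_encoder()) {
  stopifnot(inherits(truth, "corpus_ground_truth"),
            fraction > 0, fraction <= 1)
  tabs <- ground_truth_tables(truth)
  if (length(tabs) == 0) stop("ground truth contains no tables")
  cats <- vapply(tabs, `[[`, 0L, "category")
  local_seed(seed, {
    picked <- unlist(lapply(sort(unique(cats)), function(ci) {
      pool <- which(cats == ci)
      n <- round(fraction * length(pool))
      if (n < 1)
        stop("fraction ", fraction, " yields 0 seed tables for category ",
             ci)
      sort(sample(pool, n))
    }))
    tabs <- tabs[picked]
    vecs <- t(vapply(tabs, function(tb)
      encode(encoder, linearize_table(grid_table(tb$grid, tb$id))),
      numeric(encoder$d)))
    labeled_table_set(vapply(tabs, `[[`, "", "id"), vecs,
                      vapply(tabs, `[[`, "", "label"))
  })
}

ground_truth_tables <- function(truth) {
  out <- list()
  for (f in truth$files) {
    if (f$corrupted || length(f$grids) == 0) next
    for (tn in names(f$grids)) {
      out <- c(out, list(list(
        id = paste(f$article_id, f$filename, tn, sep = "/"),
        grid = f$grids[[tn]],
        category = f$category,
        label = truth$labels[[f$article_id]])))
    }
  }
  out
}

#' Serialize ground truth to JSON
#'
#' @param truth a [generate_corpus()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  tr <- truth
  tr$files <- lapply(tr$files, function(f) {
    f$grids <- lapply(f$grids, function(g) apply(g, 1, identity,
                                                 simplify = FALSE))
    f
  })
  tr$spec <- unclass(tr$spec)
  jsonlite::write_json(unclass(tr), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
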