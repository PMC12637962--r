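test_that("generation is deterministic: same seed, byte-identical tree", {
  spec <- corpus_spec(n_articles = 6, failure_rate = 0.1, seed = 77)
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  t1 <- generate_corpus(spec, d1)
  t2 <- generate_corpus(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  expect_identical(t1$expected, t2$expected)
})

test_that("an empty spec gives an empty corpus and truth", {
  tr <- generate_corpus(corpus_spec(n_articles = 0, seed = 1), tempfile("e"))
  expect_length(tr$files, 0)
  expect_identical(tr$expected$n_total, 0L)
})

test_that("planted failure counts are exact and honored by conversion", {
  spec <- corpus_spec(n_articles = 50, files_per_article = 2L,
                      failure_rate = 0.05, archive_rate = 0, seed = 31)
  dir <- tempfile("fail")
  truth <- generate_corpus(spec, dir)
  expect_identical(truth$expected$n_total, 100L)
  expect_identical(truth$expected$n_failed, 5L)   # round(0.05 * 100)
  res <- convert_corpus(load_corpus_dir(dir))
  expect_identical(res$report$n_total, truth$expected$n_total)
  expect_identical(res$report$n_failed, truth$expected$n_failed)
  expect_equal(res$report$success_rate, 0.95)
  # the corrupted files are exactly the planted ones
  planted <- sort(vapply(Filter(function(f) f$corrupted, truth$files),
                         `[[`, "", "filename"))
  expect_identical(sort(res$report$failures$filename), planted)
})

test_that("extracted grids equal ground truth cell-for-cell (incl. archives)", {
  spec <- corpus_spec(n_articles = 12, failure_rate = 0, archive_rate = 0.3,
                      seed = 19)
  dir <- tempfile("grids")
  truth <- generate_corpus(spec, dir)
  res <- convert_corpus(load_corpus_dir(dir))
  docs <- stats::setNames(res$documents,
                          vapply(res$documents, `[[`, "", "doc_id"))
  n_checked <- 0L
  for (f in truth$files) {
    if (f$media_class == "archive") next
    d <- docs[[paste0(f$article_id, "/", f$filename)]]
    expect_false(is.null(d), info = f$filename)
    tabs <- document_tables(d)
    expect_identical(length(tabs), length(f$grids), info = f$filename)
    for (tab in tabs) {
      expect_identical(table_grid(tab), unname(f$grids[[tab$table_id]]),
                       info = paste(f$filename, tab$table_id))
      n_checked <- n_checked + 1L
    }
    if (f$media_class == "pdf") {
      expect_length(tabs, 0)   # PDFs never yield tables
      paras <- vapply(d$passages, `[[`, "", "text")
      expect_identical(paras, f$paragraphs)
    }
  }
  expect_gt(n_checked, 10)
})

test_that("make_labeled_seed stratifies exactly and is reproducible", {
  spec <- corpus_spec(n_articles = 30, n_categories = 3, failure_rate = 0,
                      archive_rate = 0, seed = 23)
  dir <- tempfile("seed")
  truth <- generate_corpus(spec, dir)
  enc <- hash_encoder(64)
  ls1 <- make_labeled_seed(truth, 0.5, seed = 3, encoder = enc)
  ls2 <- make_labeled_seed(truth, 0.5, seed = 3, encoder = enc)
  expect_identical(ls1$table_ids, ls2$table_ids)
  expect_identical(ls1$vectors, ls2$vectors)
  # per-category counts are round(fraction * n_category)
  tabs <- suppbioc:::ground_truth_tables(truth)
  cats <- vapply(tabs, `[[`, 0L, "category")
  labs_all <- vapply(tabs, `[[`, "", "label")
  for (ci in sort(unique(cats))) {
    lab <- labs_all[cats == ci][1]
    expect_identical(sum(ls1$labels == lab),
                     as.integer(round(0.5 * sum(cats == ci))))
  }
  full <- make_labeled_seed(truth, 1, seed = 3, encoder = enc)
  expect_identical(length(full$table_ids), length(tabs))
  expect_error(make_labeled_seed(truth, 1e-6, seed = 3, encoder = enc),
               "0 seed tables")
})

test_that("vocabulary overlap knob keeps specs valid; disjointness enforced", {
  expect_silent(corpus_spec(n_categories = 3, overlap = 0.3))
  bad <- list(list(label = "A", vocabulary = sprintf("t%02d", 1:50)),
              list(label = "B", vocabulary = sprintf("t%02d", 1:50)))
  expect_error(corpus_spec(categories = bad), "disjoint")
})

test_that("ground truth serializes to JSON", {
  spec <- corpus_spec(n_articles = 3, seed = 5)
  truth <- generate_corpus(spec, tempfile("j"))
  p <- tempfile(fileext = ".json")
  write_ground_truth(truth, p)
  back <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(length(back$files), length(truth$files))
  expect_identical(back$expected$n_total, truth$expected$n_total)
})
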