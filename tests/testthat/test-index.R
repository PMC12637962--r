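test_that("build_index makes one entry per table in deterministic order", {
  fx <- make_seeded_index(n_articles = 3, tables_per_article = 2)
  expect_identical(nrow(fx$index$entries), 6L)
  e <- fx$index$entries
  expect_identical(order(e$article_id, e$filename, e$table_id), 1:6)
  # empty corpus -> empty index
  empty <- build_index(bioc_collection(), fx$encoder, fx$cat_set)
  expect_identical(nrow(empty$entries), 0L)
  # encoder dimension mismatch is refused
  expect_error(build_index(bioc_collection(), hash_encoder(32), fx$cat_set),
               "dimension")
})

test_that("entry codes equal standalone assign_category runs", {
  fx <- make_seeded_index(n_articles = 9)
  idx <- fx$index
  for (i in seq_len(nrow(idx$entries))) {
    solo <- assign_category(idx$vectors[i, ], fx$cat_set, tau = 0)
    expect_identical(idx$entries$code[i], solo$code)
  }
})

test_that("neighbor lists are exact, self-free and capped at min(N, n-1)", {
  fx <- make_seeded_index(n_articles = 5, tables_per_article = 1,
                          neighbors = TRUE)
  idx <- fx$index
  keys <- with(idx$entries, paste(article_id, filename, table_id, sep = "\x1f"))
  expect_identical(length(idx$neighbors), 5L)
  for (i in seq_along(idx$neighbors)) {
    nb <- idx$neighbors[[i]]
    expect_identical(nrow(nb), 4L)            # min(1000, 5 - 1)
    expect_false(keys[i] %in% nb$key)         # owner excluded
    expect_true(all(diff(nb$similarity) <= 1e-12))  # non-increasing
    # brute-force oracle
    sims <- vapply(seq_along(keys), function(j)
      cosine(idx$vectors[i, ], idx$vectors[j, ]), 0)[-i]
    expect_equal(sort(nb$similarity, decreasing = TRUE),
                 sort(sims, decreasing = TRUE), tolerance = 1e-12)
  }
})

test_that("search_by_query matches the brute-force filter+rank oracle", {
  fx <- make_seeded_index(n_articles = 15, tables_per_article = 2)
  idx <- fx$index
  q <- paste(make_category_vocab(1)[1:10], collapse = " ")
  code <- fx$truth_code[1]
  got <- search_by_query(idx, fx$encoder, q, code, top_n = 15)
  # oracle: filter entries by code, score articles by max cosine
  qv <- encode(fx$encoder, q)
  sel <- which(idx$entries$code == code)
  sims <- vapply(sel, function(j) cosine(qv, idx$vectors[j, ]), 0)
  oracle <- c(tapply(sims, idx$entries$article_id[sel], max))
  oracle <- oracle[order(-oracle, names(oracle))]   # ties by article id
  expect_identical(got$article_id, names(oracle)[seq_len(nrow(got))])
  expect_equal(got$score, as.numeric(oracle)[seq_len(nrow(got))])
  # filter soundness: every hit has >= 1 table of the requested code
  for (a in got$article_id)
    expect_true(any(idx$entries$code[idx$entries$article_id == a] == code))
})

test_that("search_by_query validates codes and handles empty filters", {
  fx <- make_seeded_index(n_articles = 3)
  expect_error(search_by_query(fx$index, fx$encoder, "q", "NOPE"),
               "unknown category code.*GPED")
  unused <- setdiff(registry_codes(), fx$index$entries$code)[1]
  out <- search_by_query(fx$index, fx$encoder, "q", unused)
  expect_identical(nrow(out), 0L)
})

test_that("a query matching one table's tokens ranks its article first at 1.0", {
  enc <- hash_encoder(64)
  cells <- list(A = c("alpha", "beta", "gamma", "delta"),
                B = c("epsilon", "zeta", "eta", "theta"),
                C = c("iota", "kappa", "lambda", "mu"))
  docs <- lapply(names(cells), function(a)
    build_document(paste0(a, "/f.csv"), "delimited_text",
                   list(sm_table(cells[[a]], 2, 2, "t1"))))
  seed_set <- structure(list(table_ids = "s1",
                             vectors = matrix(0, 1, 64),
                             codes = "GPED"),
                        class = "categorized_set")
  # zero seed vector => every best similarity is 0; tau = 0 keeps code GPED
  idx <- build_index(bioc_collection(docs), enc, seed_set, tau = 0)
  q <- paste(cells$B, collapse = " ")   # same token bag as B's table
  got <- search_by_query(idx, enc, q, "GPED", top_n = 3)
  expect_identical(got$article_id[1], "B")
  expect_equal(got$score[1], 1)
})

test_that("search_by_table equals a brute-force ranking and dedups by max", {
  fx <- make_seeded_index(n_articles = 12, tables_per_article = 2,
                          neighbors = TRUE)
  idx <- fx$index
  keys <- with(idx$entries, paste(article_id, filename, table_id, sep = "\x1f"))
  res <- search_by_table(idx, "PMC0001", "data.csv")
  own <- which(idx$entries$article_id == "PMC0001")
  # oracle: union of per-table neighbour rankings = for key j, the max
  # similarity over the file's tables i != j (siblings stay in: each list
  # only excludes its own owner)
  oracle_sim <- vapply(seq_along(keys), function(j) {
    others <- setdiff(own, j)
    max(vapply(others, function(i)
      cosine(idx$vectors[i, ], idx$vectors[j, ]), 0))
  }, 0)
  names(oracle_sim) <- keys
  # every returned key appears once
  expect_false(any(duplicated(res$key)))
  expect_true(all(diff(res$similarity) <= 1e-12))
  for (r in seq_len(nrow(res)))
    expect_equal(res$similarity[r], unname(oracle_sim[res$key[r]]),
                 tolerance = 1e-12)
  # single-table file returns exactly its neighbour list
  fx1 <- make_seeded_index(n_articles = 5, tables_per_article = 1,
                           neighbors = TRUE)
  r1 <- search_by_table(fx1$index, "PMC0002", "data.csv")
  k2 <- with(fx1$index$entries, paste(article_id, filename, table_id,
                                      sep = "\x1f"))
  i2 <- which(fx1$index$entries$article_id == "PMC0002")
  expect_identical(r1, fx1$index$neighbors[[i2]])
  expect_error(search_by_table(fx1$index, "PMC9999", "nope.csv"),
               class = "suppbioc_not_found")
})

test_that("index persistence round-trips through the versioned JSON file", {
  fx <- make_seeded_index(n_articles = 4, neighbors = TRUE, N = 5)
  path <- tempfile(fileext = ".json")
  write_index(fx$index, path)
  back <- read_index(path)
  # text persistence keeps ~15 significant digits; structure is exact
  expect_identical(back$entries[setdiff(names(back$entries), "similarity")],
                   fx$index$entries[setdiff(names(fx$index$entries),
                                            "similarity")])
  expect_equal(back$entries$similarity, fx$index$entries$similarity,
               tolerance = 1e-12)
  expect_equal(back$vectors, unname(fx$index$vectors), tolerance = 1e-12)
  expect_identical(names(back$neighbors), names(fx$index$neighbors))
  expect_equal(back$neighbors[[1]]$similarity,
               fx$index$neighbors[[1]]$similarity, tolerance = 1e-12)
  writeLines(gsub("suppbioc-index-v1", "v999", readLines(path)), path)
  expect_error(read_index(path), "version")
})

test_that("identical index and query give identical (byte-stable) results", {
  fx <- make_seeded_index(n_articles = 8)
  q <- "gene expression profile"
  a <- search_by_query(fx$index, fx$encoder, q, fx$truth_code[1], top_n = 5)
  b <- search_by_query(fx$index, fx$encoder, q, fx$truth_code[1], top_n = 5)
  expect_identical(a, b)
})
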