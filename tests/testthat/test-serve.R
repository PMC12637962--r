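make_service <- function(n_articles = 6) {
  fx <- make_seeded_index(n_articles = n_articles, neighbors = TRUE)
  docs <- lapply(seq_len(n_articles), function(ai)
    build_document(sprintf("PMC%04d/data.csv", ai), "delimited_text",
                   list(sm_table(c("a", "b"), 1, 2, "t1"))))
  list(fx = fx,
       state = service_state(fx$index, fx$encoder, bioc_collection(docs)))
}

test_that("the search route mirrors search_by_query", {
  sv <- make_service()
  r <- handle_request(sv$state, "GET", "/search",
                      list(q = "cat1word001 cat1word002",
                           code = sv$fx$truth_code[1], top = "3"))
  expect_identical(r$status, 200L)
  res <- jsonlite::fromJSON(r$body)$results
  expect_lte(nrow(res), 3)
  direct <- search_by_query(sv$fx$index, sv$fx$encoder,
                            "cat1word001 cat1word002",
                            sv$fx$truth_code[1], top_n = 3)
  expect_identical(res$article_id, direct$article_id)
  # missing parameters and unknown codes are 400s
  expect_identical(handle_request(sv$state, "GET", "/search",
                                  list(q = "x"))$status, 400L)
  expect_identical(handle_request(sv$state, "GET", "/search",
                                  list(q = "x", code = "ZZZZ"))$status, 400L)
})

test_that("the neighbors route mirrors search_by_table; unknown file is 404", {
  sv <- make_service()
  r <- handle_request(sv$state, "GET", "/neighbors",
                      list(article = "PMC0001", file = "data.csv"))
  expect_identical(r$status, 200L)
  res <- jsonlite::fromJSON(r$body)$results
  expect_true(all(diff(res$similarity) <= 1e-9))
  r404 <- handle_request(sv$state, "GET", "/neighbors",
                         list(article = "PMC9999", file = "zzz.csv"))
  expect_identical(r404$status, 404L)
})

test_that("the fetch route enforces the 50-id limit (HTTP 400-equivalent)", {
  sv <- make_service()
  ids51 <- paste(sprintf("id%02d", 1:51), collapse = ",")
  r <- handle_request(sv$state, "GET", "/fetch", list(ids = ids51))
  expect_identical(r$status, 400L)
  expect_match(jsonlite::fromJSON(r$body)$error, "50")
  r2 <- handle_request(sv$state, "GET", "/fetch",
                       list(ids = "PMC0001,PMC0002,NOPE"))
  expect_identical(r2$status, 200L)
  payload <- jsonlite::fromJSON(r2$body, simplifyVector = FALSE)
  expect_true(payload$PMC0001$found)
  expect_false(payload$NOPE$found)
  expect_false(payload$PMC0001$attachment)
})

test_that("unknown routes 404 and non-GET methods 405", {
  sv <- make_service(2)
  expect_identical(handle_request(sv$state, "GET", "/nope")$status, 404L)
  expect_identical(handle_request(sv$state, "POST", "/search")$status, 405L)
})

test_that("query strings parse with URL decoding", {
  p <- suppbioc:::parse_query_string("q=gene%20expression&code=GPED&top=5")
  expect_identical(p$q, "gene expression")
  expect_identical(p$code, "GPED")
  expect_identical(suppbioc:::parse_query_string(""), list())
})

test_that("the socket loop serves a live request", {
  sv <- make_service(3)
  port <- 40123 + (Sys.getpid() %% 1000)
  f <- parallel::mcparallel(serve_loop(sv$state, port = port,
                                       max_requests = 1))
  Sys.sleep(0.5)
  con <- tryCatch(socketConnection("127.0.0.1", port, open = "r+b",
                                   blocking = TRUE, timeout = 5),
                  error = function(e) NULL)
  if (is.null(con)) {
    parallel::mccollect(f, wait = FALSE)
    skip("could not open a loopback socket in this environment")
  }
  writeLines(sprintf("GET /search?q=x&code=%s HTTP/1.0",
                     sv$fx$truth_code[1]), con, sep = "\r\n")
  writeLines("", con, sep = "\r\n")
  resp <- readLines(con, warn = FALSE)
  close(con)
  parallel::mccollect(f)
  expect_match(resp[1], "HTTP/1.0 200")
  expect_true(any(grepl("results", resp)))
})
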