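test_that("spreadsheet bounding rectangle covers all non-empty cells", {
  # A1="g", B2="7" -> 2x2 grid with two empty cells
  wb <- write_xlsx_raw(list(S1 = matrix(c("g", "", "", "7"), 2, byrow = TRUE)))
  tabs <- extract_spreadsheet(wb)
  expect_length(tabs, 1)
  expect_identical(table_grid(tabs[[1]]),
                   matrix(c("g", "", "", "7"), 2, byrow = TRUE))
  expect_identical(tabs[[1]]$source_sheet, "S1")
  # content away from A1 anchors the rectangle at the first non-empty cell
  m <- matrix("", 4, 4); m[3, 2] <- "x"; m[4, 3] <- "y"
  tabs2 <- extract_spreadsheet(write_xlsx_raw(list(Far = m)))
  expect_identical(table_grid(tabs2[[1]]),
                   matrix(c("x", "", "", "y"), 2, byrow = TRUE))
})

test_that("multi-sheet workbooks give one table per non-empty sheet, in order", {
  wb <- write_xlsx_raw(list(
    alpha = matrix(c("a", "b"), 1),
    empty = matrix(character(0), 0, 0),
    beta = matrix(c("1", "2", "3", "4"), 2, byrow = TRUE)))
  tabs <- extract_spreadsheet(wb)
  expect_length(tabs, 2)
  expect_identical(vapply(tabs, `[[`, "", "source_sheet"), c("alpha", "beta"))
  expect_identical(vapply(tabs, `[[`, "", "table_id"), c("sheet1", "sheet3"))
})

test_that("generated numeric-as-text sheets round-trip cell-for-cell", {
  withr::with_seed(7, {
    m <- matrix(as.character(round(stats::runif(40), 4)), 10, 4)
    tabs <- extract_spreadsheet(write_xlsx_raw(list(num = m)))
    expect_identical(table_grid(tabs[[1]]), m)
  })
})

test_that("merged spreadsheet ranges duplicate the anchor value", {
  m <- matrix(c("hdr", "", "a", "b"), 2, byrow = TRUE)
  wb <- write_xlsx_raw(list(M = m),
                       merges = list(data.frame(row = 1, col = 1,
                                                nrow = 1, ncol = 2)))
  expect_identical(table_grid(extract_spreadsheet(wb)[[1]]),
                   matrix(c("hdr", "hdr", "a", "b"), 2, byrow = TRUE))
})

test_that("word-processor extraction keeps source order and expands merges", {
  tabm <- matrix(c("r1c1", "r1c2", "r2c1", "r2c2", "r3c1", "r3c2"),
                 3, 2, byrow = TRUE)
  doc <- write_docx_raw(list("first paragraph", tabm, "second paragraph"))
  res <- extract_wordproc(doc)
  expect_identical(res$paragraphs, c("first paragraph", "second paragraph"))
  expect_length(res$tables, 1)
  expect_identical(table_grid(res$tables[[1]]), tabm)
  # items preserve interleaving: paragraph, table, paragraph
  expect_identical(vapply(res$items, function(x) class(x)[1], ""),
                   c("character", "sm_table", "character"))
  # a 2-column merged header duplicates its value into both columns
  hdr <- matrix(c("merged", "ignored", "a", "b"), 2, byrow = TRUE)
  attr(hdr, "gridspan") <- data.frame(row = 1, col = 1, span = 2)
  res2 <- extract_wordproc(write_docx_raw(list(hdr)))
  expect_identical(table_grid(res2$tables[[1]])[1, ], c("merged", "merged"))
})

test_that("paragraph-only documents yield no tables", {
  res <- extract_wordproc(write_docx_raw(list("p one", "p two")))
  expect_identical(res$paragraphs, c("p one", "p two"))
  expect_identical(res$tables, list())
})

test_that("corrupt containers raise recordable conversion errors", {
  wb <- write_xlsx_raw(list(S = matrix("x", 1, 1)))
  expect_error(extract_spreadsheet(wb[1:(length(wb) - 10)]),
               class = "suppbioc_conversion_error")
  expect_error(extract_spreadsheet(charToRaw("not a zip")),
               class = "suppbioc_conversion_error")
  expect_error(extract_wordproc(write_xlsx_raw(list(S = matrix("x", 1, 1)))),
               class = "suppbioc_conversion_error")
})

test_that("slides give text-frame paragraphs and structured tables", {
  slide <- paste0(
    "<?xml version=\"1.0\"?>",
    "<p:sld xmlns:p=\"urn:x\" xmlns:a=\"urn:y\"><p:cSld><p:spTree>",
    "<p:sp><p:txBody><a:p><a:r><a:t>Slide title</a:t></a:r></a:p>",
    "<a:p><a:r><a:t>bullet</a:t></a:r></a:p></p:txBody></p:sp>",
    "<p:graphicFrame><a:tbl>",
    "<a:tr><a:tc><a:txBody><a:p><a:r><a:t>h1</a:t></a:r></a:p></a:txBody></a:tc>",
    "<a:tc><a:txBody><a:p><a:r><a:t>h2</a:t></a:r></a:p></a:txBody></a:tc></a:tr>",
    "<a:tr><a:tc gridSpan=\"2\"><a:txBody><a:p><a:r><a:t>wide</a:t></a:r></a:p>",
    "</a:txBody></a:tc></a:tr>",
    "</a:tbl></p:graphicFrame>",
    "</p:spTree></p:cSld></p:sld>")
  deck <- zip_build(list("ppt/slides/slide1.xml" = charToRaw(slide)))
  res <- extract_slides(deck)
  expect_identical(res$paragraphs, c("Slide title", "bullet"))
  expect_length(res$tables, 1)
  expect_identical(table_grid(res$tables[[1]]),
                   matrix(c("h1", "h2", "wide", "wide"), 2, byrow = TRUE))
})
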