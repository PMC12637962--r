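test_that("empty collection serializes to minimal XML and JSON", {
  coll <- bioc_collection()
  xml <- write_bioc_xml(coll)
  expect_match(xml, "<collection>")
  expect_identical(read_bioc_xml(xml)$documents, list())
  js <- write_bioc_json(coll)
  expect_identical(read_bioc_json(js)$documents, list())
})

test_that("a 2x2 table writes exactly 4 cell annotations with row/col infons", {
  d <- build_document("PMC1/t.csv", "delimited_text",
                      list(sm_table(c("a", "b", "1", "2"), 2, 2, "t1")))
  xml <- write_bioc_xml(bioc_collection(list(d)))
  x <- xml2::read_xml(xml)
  anns <- xml2::xml_find_all(x, "//annotation")
  expect_length(anns, 4)
  rc <- t(vapply(anns, function(a) {
    inf <- xml2::xml_find_all(a, "infon")
    v <- xml2::xml_text(inf); names(v) <- xml2::xml_attr(inf, "key")
    c(v[["row"]], v[["col"]])
  }, c("", "")))
  expect_setequal(paste(rc[, 1], rc[, 2]), c("0 0", "0 1", "1 0", "1 1"))
})

test_that("hand-written minimal BioC XML with a 1x3 table parses", {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<collection>\n',
    "<source>s</source><date></date><key>k</key>\n<document>\n",
    "<id>PMCX/f.tsv</id><infon key=\"media_class\">delimited_text</infon>\n",
    "<passage><infon key=\"type\">table</infon>",
    "<infon key=\"table_id\">t9</infon>",
    "<infon key=\"n_rows\">1</infon><infon key=\"n_cols\">3</infon>",
    "<offset>0</offset><text>aa\tb\tccc</text>",
    '<annotation id="r0c0"><infon key="type">cell</infon>',
    '<infon key="row">0</infon><infon key="col">0</infon>',
    '<location offset="0" length="2"/><text>aa</text></annotation>',
    '<annotation id="r0c1"><infon key="type">cell</infon>',
    '<infon key="row">0</infon><infon key="col">1</infon>',
    '<location offset="3" length="1"/><text>b</text></annotation>',
    '<annotation id="r0c2"><infon key="type">cell</infon>',
    '<infon key="row">0</infon><infon key="col">2</infon>',
    '<location offset="5" length="3"/><text>ccc</text></annotation>',
    "</passage></document></collection>")
  coll <- read_bioc_xml(xml)
  tabs <- document_tables(coll$documents[[1]])
  expect_length(tabs, 1)
  expect_identical(dim(tabs[[1]]), c(1L, 3L))
  expect_identical(tabs[[1]]$cells, c("aa", "b", "ccc"))
})

test_that("annotation spans outside the passage text are rejected on read", {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<collection>',
    "<source>s</source><date></date><key>k</key><document>",
    "<id>d</id><infon key=\"media_class\">plain_text</infon>",
    "<passage><infon key=\"type\">table</infon>",
    "<infon key=\"table_id\">t</infon>",
    "<infon key=\"n_rows\">1</infon><infon key=\"n_cols\">1</infon>",
    "<offset>0</offset><text>ab</text>",
    '<annotation id="r0c0"><infon key="type">cell</infon>',
    '<infon key="row">0</infon><infon key="col">0</infon>',
    '<location offset="0" length="9"/><text>ab</text></annotation>',
    "</passage></document></collection>")
  expect_error(read_bioc_xml(xml), "outside|span")
})

test_that("malformed XML raises a parse error", {
  expect_error(read_bioc_xml("<collection><document>"), ".")
})

test_that("round-trips are lossless and deterministic on a randomized corpus", {
  coll <- random_collection(50, seed = 424242)
  xml <- write_bioc_xml(coll)
  expect_identical(read_bioc_xml(xml), coll)           # XML round-trip
  js <- write_bioc_json(coll)
  expect_identical(read_bioc_json(js), coll)           # JSON round-trip
  # XML -> model -> JSON -> model -> XML is byte-identical
  expect_identical(write_bioc_xml(read_bioc_json(js)), xml)
  # determinism: writing twice is byte-identical
  expect_identical(write_bioc_xml(coll), xml)
  expect_identical(write_bioc_json(coll), js)
  # cell reconstruction across every table passage
  for (d in coll$documents) {
    for (p in d$passages) {
      if (p$passage_type == "table") {
        tab <- passage_table(p)
        expect_identical(length(tab$cells), tab$n_rows * tab$n_cols)
      }
    }
  }
})

test_that("unknown infons survive the round-trip verbatim", {
  d <- build_document("PMC9/f.txt", "plain_text", list("hello"),
                      infons = c(zeta = "1", alpha = "two & <three>"))
  coll <- bioc_collection(list(d))
  for (rt in list(read_bioc_xml(write_bioc_xml(coll)),
                  read_bioc_json(write_bioc_json(coll)))) {
    expect_identical(rt$documents[[1]]$infons,
                     c(alpha = "two & <three>", zeta = "1"))
  }
})
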