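# Minimal OOXML writers: enough of a spreadsheet / word-processor container
# to round-trip grids through the extractors. Inline strings only (no
# sharedStrings), one XML part per sheet, fixed part order => deterministic
# bytes via zip_build().

col_letter <- function(j) {
  # 1-based column index -> A1-style letters
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

letter_col <- function(s) {
  ch <- utf8ToInt(s) - utf8ToInt("A") + 1L
  Reduce(function(a, b) a * 26L + b, ch, accumulate = FALSE)
}

split_cellref <- function(ref) {
  # "BC12" -> c(col, row), 1-based
  m <- regmatches(ref, regexec("^([A-Z]+)([0-9]+)$", ref))[[1]]
  c(letter_col(m[2]), as.integer(m[3]))
}

XML_DECL <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>\n"

#' Write a minimal OOXML spreadsheet
#'
#' One worksheet per element of `sheets`; every cell is written as an inline
#' string. Optional merged ranges duplicate nothing on disk (only the anchor
#' cell holds the value) — expansion happens in [extract_spreadsheet()].
#'
#' @param sheets named list of character matrices (sheet name -> grid).
#' @param merges optional list (parallel to `sheets`) of data.frames with
#'   columns `row`, `col`, `nrow`, `ncol` (1-based anchors and extents).
#' @return Raw vector holding the `.xlsx` container.
#' @export
write_xlsx_raw <- function(sheets, merges = NULL) {
  stopifnot(length(sheets) >= 1, !is.null(names(sheets)))
  ns_main <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  ns_rel <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
  n <- length(sheets)
  members <- list()
  members[["[Content_Types].xml"]] <- charToRaw(paste0(
    XML_DECL,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    paste0(sprintf("<Override PartName=\"/xl/worksheets/sheet%d.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
                   seq_len(n)), collapse = ""),
    "</Types>"))
  members[["_rels/.rels"]] <- charToRaw(paste0(
    XML_DECL,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"", ns_rel, "/officeDocument\" Target=\"xl/workbook.xml\"/>",
    "</Relationships>"))
  members[["xl/workbook.xml"]] <- charToRaw(paste0(
    XML_DECL,
    "<workbook xmlns=\"", ns_main, "\" xmlns:r=\"", ns_rel, "\"><sheets>",
    paste0(sprintf("<sheet name=\"%s\" sheetId=\"%d\" r:id=\"rId%d\"/>",
                   xml_escape_attr(names(sheets)), seq_len(n), seq_len(n)),
           collapse = ""),
    "</sheets></workbook>"))
  members[["xl/_rels/workbook.xml.rels"]] <- charToRaw(paste0(
    XML_DECL,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    paste0(sprintf("<Relationship Id=\"rId%d\" Type=\"%s/worksheet\" Target=\"worksheets/sheet%d.xml\"/>",
                   seq_len(n), ns_rel, seq_len(n)), collapse = ""),
    "</Relationships>"))
  for (i in seq_len(n)) {
    m <- sheets[[i]]
    rows <- character(0)
    if (length(m) > 0 && nrow(m) > 0) {
      rows <- vapply(seq_len(nrow(m)), function(r) {
        cells <- vapply(seq_len(ncol(m)), function(cc) {
          v <- m[r, cc]
          if (is.na(v) || identical(v, "")) return("")
          sprintf("<c r=\"%s%d\" t=\"inlineStr\"><is><t xml:space=\"preserve\">%s</t></is></c>",
                  col_letter(cc), r, xml_escape_text(v))
        }, "")
        sprintf("<row r=\"%d\">%s</row>", r, paste(cells, collapse = ""))
      }, "")
    }
    merge_xml <- ""
    mg <- if (!is.null(merges)) merges[[i]] else NULL
    if (!is.null(mg) && nrow(mg) > 0) {
      refs <- sprintf("<mergeCell ref=\"%s%d:%s%d\"/>",
                      vapply(mg$col, col_letter, ""), mg$row,
                      vapply(mg$col + mg$ncol - 1L, col_letter, ""),
                      mg$row + mg$nrow - 1L)
      merge_xml <- sprintf("<mergeCells count=\"%d\">%s</mergeCells>",
                           nrow(mg), paste(refs, collapse = ""))
    }
    members[[sprintf("xl/worksheets/sheet%d.xml", i)]] <- charToRaw(paste0(
      XML_DECL, "<worksheet xmlns=\"", ns_main, "\"><sheetData>",
      paste(rows, collapse = ""), "</sheetData>", merge_xml, "</worksheet>"))
  }
  zip_build(members)
}

#' Write a minimal OOXML word-processor document
#'
#' @param items list, in document order, of character scalars (paragraphs) and
#'   tables. A table is a character matrix, optionally carrying a `gridspan`
#'   attribute: a data.frame with 1-based columns `row`, `col`, `span` marking
#'   horizontally merged cells (the anchor cell spans `span` columns; covered
#'   cells are omitted from the container, as word processors do).
#' @return Raw vector holding the `.docx` container.
#' @export
write_docx_raw <- function(items) {
  ns_w <- "http://schemas.openxmlformats.org/wordprocessingml/2006/main"
  body <- vapply(items, function(it) {
    if (is.character(it) && is.null(dim(it))) {
      sprintf("<w:p><w:r><w:t xml:space=\"preserve\">%s</w:t></w:r></w:p>",
              xml_escape_text(it))
    } else {
      m <- it
      gs <- attr(m, "gridspan")
      trs <- vapply(seq_len(nrow(m)), function(r) {
        tcs <- character(0)
        cc <- 1L
        while (cc <= ncol(m)) {
          span <- 1L
          if (!is.null(gs)) {
            hit <- gs$row == r & gs$col == cc
            if (any(hit)) span <- gs$span[which(hit)[1]]
          }
          prop <- if (span > 1L)
            sprintf("<w:tcPr><w:gridSpan w:val=\"%d\"/></w:tcPr>", span)
          else ""
          tcs <- c(tcs, sprintf(
            "<w:tc>%s<w:p><w:r><w:t xml:space=\"preserve\">%s</w:t></w:r></w:p></w:tc>",
            prop, xml_escape_text(m[r, cc])))
          cc <- cc + span
        }
        sprintf("<w:tr>%s</w:tr>", paste(tcs, collapse = ""))
      }, "")
      sprintf("<w:tbl>%s</w:tbl>", paste(trs, collapse = ""))
    }
  }, "")
  members <- list()
  members[["[Content_Types].xml"]] <- charToRaw(paste0(
    XML_DECL,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/word/document.xml\" ContentType=\"application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml\"/>",
    "</Types>"))
  members[["_rels/.rels"]] <- charToRaw(paste0(
    XML_DECL,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" Target=\"word/document.xml\"/>",
    "</Relationships>"))
  members[["word/document.xml"]] <- charToRaw(paste0(
    XML_DECL, "<w:document xmlns:w=\"", ns_w, "\"><w:body>",
    paste(body, collapse = ""), "</w:body></w:document>"))
  zip_build(members)
}
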