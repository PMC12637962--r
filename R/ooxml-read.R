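# Readers for OOXML containers (spreadsheet / word-processor / slides),
# implemented over unzip + xml2. Corrupt containers raise
# suppbioc_conversion_error conditions, which convert_corpus() records as
# failures rather than propagating.

conversion_error <- function(msg, class = character(0)) {
  stop(errorCondition(msg, class = c(class, "suppbioc_conversion_error",
                                     "error")))
}

ooxml_parts <- function(payload, what) {
  if (!is_zip_payload(payload))
    conversion_error(paste0("not an OOXML container (", what,
                            "): bad signature"))
  tryCatch(
    withCallingHandlers(zip_members(payload),
                        warning = function(w) stop(conditionMessage(w))),
    error = function(e)
      conversion_error(paste0("corrupt ", what, " container: ",
                              conditionMessage(e))))
}

part_xml <- function(parts, name, what) {
  if (!name %in% names(parts))
    conversion_error(paste0("corrupt ", what, " container: missing ", name))
  tryCatch(xml2::read_xml(parts[[name]]),
           error = function(e)
             conversion_error(paste0("corrupt ", what, " part ", name, ": ",
                                     conditionMessage(e))))
}

#' Extract tables from an OOXML spreadsheet
#'
#' One table per non-empty sheet, in workbook order. The grid is the minimal
#' rectangle covering all non-empty cells; merged ranges are expanded by
#' duplicating the anchor value into every covered position; numeric cells
#' are rendered as text. Sheet names are recorded in `source_sheet`.
#'
#' @param payload raw vector holding an `.xlsx` container.
#' @param id_prefix prefix for generated table ids (`<prefix><sheet index>`).
#' @return List of [sm_table()] objects.
#' @export
extract_spreadsheet <- function(payload, id_prefix = "sheet") {
  parts <- ooxml_parts(payload, "spreadsheet")
  wb <- part_xml(parts, "xl/workbook.xml", "spreadsheet")
  sheets <- xml2::xml_find_all(wb, ".//*[local-name()='sheet']")
  nm <- xml2::xml_attr(sheets, "name")
  rid <- xml2::xml_attr(sheets, "id", ns = character(0))
  # resolve r:id -> worksheet part via the workbook rels when present;
  # fall back to positional sheetN.xml naming
  targets <- sprintf("xl/worksheets/sheet%d.xml", seq_along(sheets))
  if ("xl/_rels/workbook.xml.rels" %in% names(parts)) {
    rels <- part_xml(parts, "xl/_rels/workbook.xml.rels", "spreadsheet")
    rel_nodes <- xml2::xml_find_all(rels,
                                    ".//*[local-name()='Relationship']")
    rel_map <- stats::setNames(xml2::xml_attr(rel_nodes, "Target"),
                               xml2::xml_attr(rel_nodes, "Id"))
    rids <- vapply(sheets, function(s) {
      v <- xml2::xml_attrs(s)
      idx <- grep("(^|:)id$", names(v))
      if (length(idx) > 0) v[[idx[1]]] else NA_character_
    }, "")
    hit <- !is.na(rids) & rids %in% names(rel_map)
    targets[hit] <- file.path("xl", sub("^/?", "", rel_map[rids[hit]]))
  }
  shared <- character(0)
  if ("xl/sharedStrings.xml" %in% names(parts)) {
    ss <- part_xml(parts, "xl/sharedStrings.xml", "spreadsheet")
    shared <- vapply(xml2::xml_find_all(ss, ".//*[local-name()='si']"),
                     xml2::xml_text, "")
  }
  out <- list()
  for (i in seq_along(sheets)) {
    if (!targets[i] %in% names(parts)) next
    ws <- part_xml(parts, targets[i], "spreadsheet")
    tab <- read_worksheet(ws, shared, sprintf("%s%d", id_prefix, i), nm[i])
    if (!is.null(tab)) out <- c(out, list(tab))
  }
  out
}

read_worksheet <- function(ws, shared, table_id, sheet_name) {
  cells <- xml2::xml_find_all(ws, ".//*[local-name()='c']")
  if (length(cells) == 0) return(NULL)
  refs <- xml2::xml_attr(cells, "r")
  types <- xml2::xml_attr(cells, "t")
  vals <- vapply(seq_along(cells), function(i) {
    ty <- types[i]
    if (!is.na(ty) && ty == "inlineStr") {
      xml2::xml_text(xml2::xml_find_first(cells[[i]],
                                          ".//*[local-name()='is']"))
    } else if (!is.na(ty) && ty == "s") {
      idx <- as.integer(xml2::xml_text(
        xml2::xml_find_first(cells[[i]], ".//*[local-name()='v']"))) + 1L
      if (idx >= 1 && idx <= length(shared)) shared[idx] else ""
    } else {
      v <- xml2::xml_find_first(cells[[i]], ".//*[local-name()='v']")
      if (inherits(v, "xml_missing")) "" else render_cell_text(xml2::xml_text(v))
    }
  }, "")
  rc <- t(vapply(refs, split_cellref, c(0L, 0L)))
  keep <- !is.na(vals) & nzchar(vals)
  # merged ranges make their covered positions "occupied" by the anchor value
  merges <- xml2::xml_find_all(ws, ".//*[local-name()='mergeCell']")
  extra <- list()
  for (mc in merges) {
    ref <- strsplit(xml2::xml_attr(mc, "ref"), ":", fixed = TRUE)[[1]]
    if (length(ref) != 2) next
    a <- split_cellref(ref[1]); b <- split_cellref(ref[2])
    hit <- which(rc[, 1] == a[1] & rc[, 2] == a[2] & keep)
    if (length(hit) == 0) next
    v <- vals[hit[1]]
    for (col in a[1]:b[1]) for (row in a[2]:b[2]) {
      if (col == a[1] && row == a[2]) next
      extra[[length(extra) + 1L]] <- list(col = col, row = row, val = v)
    }
  }
  if (length(extra) > 0) {
    rc <- rbind(rc[keep, , drop = FALSE],
                t(vapply(extra, function(e) c(e$col, e$row), c(0L, 0L))))
    vals <- c(vals[keep], vapply(extra, `[[`, "", "val"))
  } else {
    rc <- rc[keep, , drop = FALSE]
    vals <- vals[keep]
  }
  if (nrow(rc) == 0) return(NULL)
  r0 <- min(rc[, 2]); r1 <- max(rc[, 2])
  c0 <- min(rc[, 1]); c1 <- max(rc[, 1])
  m <- matrix("", r1 - r0 + 1L, c1 - c0 + 1L)
  m[cbind(rc[, 2] - r0 + 1L, rc[, 1] - c0 + 1L)] <- vals
  grid_table(m, table_id, source_sheet = sheet_name)
}

render_cell_text <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) return(v)
  if (num == floor(num) && abs(num) < 1e15)
    return(format(num, scientific = FALSE, trim = TRUE))
  # shortest decimal text that round-trips the double
  for (d in 1:17) {
    s <- formatC(num, digits = d, format = "g")
    if (as.numeric(s) == num) return(s)
  }
  as.character(num)
}

#' Extract paragraphs and tables from an OOXML word-processor document
#'
#' Body children are walked in document order. Merged cells are expanded by
#' value duplication: `gridSpan` horizontally, `vMerge` continuation cells
#' vertically. Ragged rows are right-padded with empty cells.
#'
#' @param payload raw vector holding a `.docx` container.
#' @param id_prefix prefix for generated table ids.
#' @return List with `paragraphs` (character vector), `tables` (list of
#'   [sm_table()]) and `items` (both, interleaved in source order).
#' @export
extract_wordproc <- function(payload, id_prefix = "tbl") {
  parts <- ooxml_parts(payload, "word-processor")
  doc <- part_xml(parts, "word/document.xml", "word-processor")
  body <- xml2::xml_find_first(doc, ".//*[local-name()='body']")
  if (inherits(body, "xml_missing"))
    conversion_error("corrupt word-processor document: no body")
  items <- list(); tid <- 0L
  for (child in xml2::xml_children(body)) {
    nmc <- xml2::xml_name(child)
    if (nmc == "p") {
      items <- c(items, list(xml2::xml_text(child)))
    } else if (nmc == "tbl") {
      tid <- tid + 1L
      items <- c(items, list(read_w_table(child, sprintf("%s%d", id_prefix,
                                                         tid))))
    }
  }
  list(paragraphs = unlist(Filter(is.character, items)) %||% character(0),
       tables = Filter(function(x) inherits(x, "sm_table"), items),
       items = items)
}

read_w_table <- function(tbl, table_id) {
  rows <- xml2::xml_find_all(tbl, "./*[local-name()='tr']")
  grid <- list()
  for (ri in seq_along(rows)) {
    cells <- xml2::xml_find_all(rows[[ri]], "./*[local-name()='tc']")
    vals <- character(0)
    for (tc in cells) {
      span <- xml2::xml_find_first(tc, ".//*[local-name()='gridSpan']")
      k <- if (inherits(span, "xml_missing")) 1L
           else as.integer(xml2::xml_attr(span, "val"))
      vm <- xml2::xml_find_first(tc, ".//*[local-name()='vMerge']")
      v <- xml2::xml_text(tc)
      if (!inherits(vm, "xml_missing")) {
        vmv <- xml2::xml_attr(vm, "val")
        if (is.na(vmv) || vmv == "continue") {
          # vertical-merge continuation: duplicate the value from above
          col <- length(vals) + 1L
          v <- if (ri > 1 && col <= length(grid[[ri - 1L]]))
            grid[[ri - 1L]][col] else v
        }
      }
      vals <- c(vals, rep(v, k))
    }
    grid[[ri]] <- vals
  }
  rows_to_table(grid, table_id)
}

#' Extract paragraphs and tables from an OOXML slide deck
#'
#' Text-frame paragraphs and embedded tables, slide by slide in deck order.
#'
#' @param payload raw vector holding a `.pptx` container.
#' @param id_prefix prefix for generated table ids.
#' @return Same shape as [extract_wordproc()].
#' @export
extract_slides <- function(payload, id_prefix = "slidetbl") {
  parts <- ooxml_parts(payload, "slides")
  slide_names <- grep("^ppt/slides/slide[0-9]+\\.xml$", names(parts),
                      value = TRUE)
  ord <- order(as.integer(sub("^ppt/slides/slide([0-9]+)\\.xml$", "\\1",
                              slide_names)))
  items <- list(); tid <- 0L
  for (nm in slide_names[ord]) {
    sl <- part_xml(parts, nm, "slides")
    for (tbl in xml2::xml_find_all(sl, ".//*[local-name()='tbl']")) {
      tid <- tid + 1L
      items <- c(items, list(read_a_table(tbl, sprintf("%s%d", id_prefix,
                                                       tid))))
    }
    paras <- xml2::xml_find_all(sl, paste0(
      ".//*[local-name()='txBody'][not(ancestor::*[local-name()='tbl'])]",
      "//*[local-name()='p']"))
    for (p in paras) {
      txt <- xml2::xml_text(p)
      if (nzchar(txt)) items <- c(items, list(txt))
    }
  }
  list(paragraphs = unlist(Filter(is.character, items)) %||% character(0),
       tables = Filter(function(x) inherits(x, "sm_table"), items),
       items = items)
}

read_a_table <- function(tbl, table_id) {
  rows <- xml2::xml_find_all(tbl, "./*[local-name()='tr']")
  grid <- lapply(rows, function(tr) {
    cells <- xml2::xml_find_all(tr, "./*[local-name()='tc']")
    unlist(lapply(cells, function(tc) {
      k <- xml2::xml_attr(tc, "gridSpan")
      k <- if (is.na(k)) 1L else as.integer(k)
      rep(xml2::xml_text(tc), k)
    })) %||% character(0)
  })
  rows_to_table(grid, table_id)
}
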