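#' Rectangular text table
#'
#' The atomic unit of categorization and retrieval: a rectangular grid of text
#' cells with an optional caption, as recovered from a supplementary file.
#' Cells are stored row-major as a character vector of length
#' `n_rows * n_cols`; empty cells are empty strings, never absent.
#'
#' @param cells character vector, row-major, length `n_rows * n_cols`.
#' @param n_rows,n_cols non-negative integers. `n_rows == 0` iff `n_cols == 0`.
#' @param table_id identifier, unique within its document.
#' @param caption optional caption text (`NULL` for none).
#' @param source_sheet optional spreadsheet sheet name.
#' @return An object of class `sm_table`.
#' @examples
#' sm_table(c("gene", "fc", "BRCA1", "2.5"), 2, 2, "t1")
#' @export
sm_table <- function(cells, n_rows, n_cols, table_id,
                     caption = NULL, source_sheet = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  cells <- as.character(cells)
  x <- structure(
    list(table_id = as.character(table_id),
         caption = if (is.null(caption)) NULL else as.character(caption),
         n_rows = n_rows, n_cols = n_cols,
         cells = cells,
         source_sheet = if (is.null(source_sheet)) NULL
                        else as.character(source_sheet)),
    class = "sm_table")
  validate_sm_table(x)
  x
}

#' Validate an sm_table's invariants
#'
#' Checks the cell count against the declared shape, the empty-shape rule
#' (`n_rows == 0` iff `n_cols == 0`) and that no cell is `NA`.
#'
#' @param x an `sm_table`.
#' @return `x`, invisibly; errors name the offending table.
#' @export
validate_sm_table <- function(x) {
  stopifnot(inherits(x, "sm_table"))
  if (is.na(x$n_rows) || is.na(x$n_cols) || x$n_rows < 0L || x$n_cols < 0L)
    stop("sm_table '", x$table_id, "': negative or missing dimensions")
  if ((x$n_rows == 0L) != (x$n_cols == 0L))
    stop("sm_table '", x$table_id, "': n_rows = 0 iff n_cols = 0 violated")
  if (length(x$cells) != x$n_rows * x$n_cols)
    stop("sm_table '", x$table_id, "': ", length(x$cells),
         " cells for a ", x$n_rows, "x", x$n_cols, " grid")
  if (anyNA(x$cells))
    stop("sm_table '", x$table_id, "': NA cells (empty cells must be \"\")")
  invisible(x)
}

#' @export
print.sm_table <- function(x, ...) {
  cat("<sm_table> ", x$table_id, ": ", x$n_rows, " x ", x$n_cols, sep = "")
  if (!is.null(x$source_sheet)) cat(" [sheet: ", x$source_sheet, "]", sep = "")
  if (!is.null(x$caption)) cat("\n  caption: ", x$caption, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.sm_table <- function(x) c(x$n_rows, x$n_cols)

#' Cell grid as a character matrix
#'
#' @param x an `sm_table`.
#' @return `n_rows` x `n_cols` character matrix (row-major fill).
#' @export
table_grid <- function(x) {
  validate_sm_table(x)
  matrix(x$cells, nrow = x$n_rows, ncol = x$n_cols, byrow = TRUE)
}

#' Build an sm_table from a character matrix
#'
#' @param m character matrix (or something coercible).
#' @inheritParams sm_table
#' @return An `sm_table`.
#' @export
grid_table <- function(m, table_id, caption = NULL, source_sheet = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "character"
  m[is.na(m)] <- ""
  sm_table(as.vector(t(m)), nrow(m), ncol(m), table_id,
           caption = caption, source_sheet = source_sheet)
}
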