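# Randomized BioC documents for round-trip testing. Cell/paragraph text draws
# from a charset that exercises XML/JSON escaping (&, <, >, quotes, tabs,
# newlines, unicode); carriage returns are excluded (rejected by the model).

rand_text <- function(n_max = 12, allow_empty = TRUE) {
  chars <- c(letters, LETTERS, 0:9, " ", "&", "<", ">", "\"", "'", ",", ";",
             "\t", "\n", "é", "α", "%", "|", "/")
  n <- sample.int(n_max + 1, 1) - 1L
  if (!allow_empty && n == 0L) n <- 1L
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

rand_table <- function(id) {
  if (runif(1) < 0.08) {
    nr <- 0L; nc <- 0L
  } else {
    nr <- sample.int(6, 1); nc <- sample.int(5, 1)
  }
  cells <- vapply(seq_len(nr * nc), function(i) rand_text(8), "")
  sm_table(cells, nr, nc, id,
           caption = if (runif(1) < 0.4) rand_text(20, allow_empty = FALSE),
           source_sheet = if (runif(1) < 0.3) paste0("Sheet", sample.int(3, 1)))
}

rand_document <- function(i) {
  n_items <- sample.int(4, 1)
  tid <- 0L
  items <- lapply(seq_len(n_items), function(j) {
    if (runif(1) < 0.5) {
      tid <<- tid + 1L
      rand_table(sprintf("tab%d", tid))
    } else rand_text(30)
  })
  infons <- c(url = sprintf("file:///sm/%03d", i))
  if (runif(1) < 0.5) infons <- c(infons, note = rand_text(10))
  build_document(sprintf("PMC%06d/file_%02d.xlsx", i, i %% 7),
                 sample(c("spreadsheet", "delimited_text", "word_processor"), 1),
                 items, infons = infons, title_first = runif(1) < 0.3)
}

random_collection <- function(n, seed) {
  withr::with_seed(seed, bioc_collection(lapply(seq_len(n), rand_document)))
}
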