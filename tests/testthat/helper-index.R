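# Seeded fixture: a categorized corpus + index built from category-specific
# vocabularies through the real pipeline (encode -> cluster -> assign).

CATEGORY_LABELS <- c("Gene Expression Data",
                     "Cohort and Patient Characteristics",
                     "Genomic Mutation and Variant Data")

make_category_vocab <- function(ci) sprintf("cat%dword%03d", ci, 1:40)

make_seeded_index <- function(n_articles = 20, tables_per_article = 2,
                              d = 128, seed = 101, tau = 0, neighbors = FALSE,
                              N = 1000) {
  enc <- hash_encoder(d)
  withr::with_seed(seed, {
    # seed set: 12 labeled tables per category
    seed_vecs <- list(); seed_ids <- character(0); seed_labels <- character(0)
    for (ci in seq_along(CATEGORY_LABELS)) {
      for (j in 1:12) {
        txt <- paste(sample(make_category_vocab(ci), 25, TRUE), collapse = " ")
        seed_vecs[[length(seed_vecs) + 1L]] <- encode(enc, txt)
        seed_ids <- c(seed_ids, sprintf("seed-c%d-%02d", ci, j))
        seed_labels <- c(seed_labels, CATEGORY_LABELS[ci])
      }
    }
    lset <- labeled_table_set(seed_ids, do.call(rbind, seed_vecs), seed_labels)
    model <- fit_cluster_model(lset, k = length(CATEGORY_LABELS), seed = seed,
                               tau = tau)
    cat_set <- categorized_tables(model, lset)
    docs <- lapply(seq_len(n_articles), function(ai) {
      ci <- (ai - 1) %% length(CATEGORY_LABELS) + 1
      items <- lapply(seq_len(tables_per_article), function(ti) {
        m <- matrix(sample(make_category_vocab(ci), 12, TRUE), 4, 3)
        grid_table(m, sprintf("t%d", ti))
      })
      build_document(sprintf("PMC%04d/data.csv", ai), "delimited_text", items)
    })
    idx <- build_index(bioc_collection(docs), enc, cat_set, tau = tau)
    if (neighbors) idx <- precompute_neighbors(idx, N)
    list(index = idx, encoder = enc, model = model, cat_set = cat_set,
         truth_code = model$code[
           model$assignment[match(CATEGORY_LABELS,
                                  seed_labels)]])
  })
}
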