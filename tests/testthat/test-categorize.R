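test_that("cluster naming: modal label, lexicographic ties, registry codes", {
  labels <- c("A", "A", "A", "B", "Gene Expression Data",
              "Gene Expression Data", "B", "B", "A", "B")
  assignment <- c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)
  nm <- name_clusters(assignment, labels, k = 3)
  expect_identical(nm$representative[1], "A")       # {A:3, B:1}
  expect_identical(nm$representative[2], "Gene Expression Data")
  expect_identical(nm$code[2], "GPED")              # registry lookup
  # cluster 3 has {B:3, A:1} -> B
  expect_identical(nm$representative[3], "B")
  # exact tie goes to the lexicographically smaller label
  tie <- name_clusters(c(1L, 1L, 1L, 1L), c("B", "A", "B", "A"), k = 1)
  expect_identical(tie$representative, "A")
})

test_that("generated codes are 4-letter consonant-preferring and unique", {
  expect_identical(label_code("Proteomics Data"), "PRTM")
  expect_identical(label_code("Proteomics Data", existing = "PRTM"), "PRT2")
  expect_identical(label_code("Aioe"), "AIOE")      # all vowels fall through
  expect_identical(label_code("Xy"), "XYXX")        # short labels padded
  # the reserved Other code is never produced
  expect_false(identical(label_code("Other"), "OTHR"))
  reg <- load_code_registry()
  expect_identical(unname(reg[["Gene Expression Data"]]), "GPED")
  expect_identical(length(reg), 14L)
})

test_that("assign_category equals the brute-force 1-NN oracle (200x50)", {
  withr::with_seed(60, {
    d <- 32
    ref <- matrix(stats::rnorm(200 * d), 200, d)
    ids <- sprintf("t%03d", sample(200))
    codes <- sample(c("GPED", "CPC", "MAV", "FAPA"), 200, TRUE)
    cat_set <- structure(list(table_ids = ids, vectors = ref, codes = codes),
                         class = "categorized_set")
    q <- matrix(stats::rnorm(50 * d), 50, d)
    got <- assign_category(q, cat_set, tau = 0)
    for (i in 1:50) {
      sims <- vapply(1:200, function(j) cosine(q[i, ], ref[j, ]), 0)
      best <- max(sims)
      jbest <- which(sims == best)
      jbest <- jbest[order(ids[jbest])][1]   # ties by smaller table_id
      expect_equal(got$similarity[i], best)
      expect_identical(got$code[i], codes[jbest])
    }
  })
})

test_that("tau thresholding: identical vector hits 1.0; low sims go OTHR", {
  ref <- diag(1, 3, 8)
  cat_set <- structure(list(table_ids = c("a", "b", "c"), vectors = ref,
                            codes = c("GPED", "CPC", "MAV")),
                       class = "categorized_set")
  hit <- assign_category(ref[2, ], cat_set, tau = 0.3)
  expect_identical(hit$code, "CPC")
  expect_equal(hit$similarity, 1)
  ortho <- c(0, 0, 0, 1, 0, 0, 0, 0)
  miss <- assign_category(ortho, cat_set, tau = 0.3)
  expect_identical(miss$code, "OTHR")
  expect_equal(miss$similarity, 0)
  expect_error(assign_category(ref[1, ],
    structure(list(table_ids = character(0),
                   vectors = matrix(0, 0, 8), codes = character(0)),
              class = "categorized_set")), "empty")
  expect_error(assign_category(c(1, 0), cat_set), "dimension")
})

test_that("the Other fraction is monotone non-decreasing in tau", {
  withr::with_seed(61, {
    ref <- matrix(stats::rnorm(40 * 16), 40, 16)
    cat_set <- structure(list(table_ids = sprintf("t%02d", 1:40),
                              vectors = ref,
                              codes = rep(c("GPED", "CPC"), 20)),
                         class = "categorized_set")
    q <- matrix(stats::rnorm(30 * 16), 30, 16)
    fracs <- vapply(seq(0, 1, by = 0.1), function(tau)
      mean(assign_category(q, cat_set, tau = tau)$code == "OTHR"), 0)
    expect_true(all(diff(fracs) >= 0))
  })
})

test_that("calibrate_tau realizes approximately the target Other fraction", {
  withr::with_seed(62, {
    sims <- stats::runif(500, 0.1, 0.9)
    tau <- calibrate_tau(sims, 0.01)
    expect_lte(mean(sims < tau), 0.01)
    expect_gte(mean(sims <= tau), 0.01)
  })
})

test_that("weighted model fitting groups labels and maps tables to clusters", {
  enc <- hash_encoder(96)
  withr::with_seed(63, {
    vocabs <- list(g = sprintf("gene%02d", 1:30),
                   c = sprintf("clin%02d", 1:30),
                   m = sprintf("metab%02d", 1:30))
    labels <- c("Gene Expression Data", "Cohort and Patient Characteristics",
                "Metabolomics and Lipidomic Data")
    n_per <- 15
    vecs <- do.call(rbind, lapply(1:3, function(ci)
      t(replicate(n_per, encode(enc,
        paste(sample(vocabs[[ci]], 20, TRUE), collapse = " "))))))
    lset <- labeled_table_set(sprintf("t%02d", seq_len(3 * n_per)), vecs,
                              rep(labels, each = n_per))
    model <- fit_cluster_model(lset, k = 3, seed = 5, tau = 0.1)
    expect_identical(model$k, 3L)
    expect_setequal(model$representative, labels)
    expect_true("GPED" %in% model$code)
    expect_false(OTHR <- "OTHR" %in% model$code)
    # every table of one label lands in one cluster
    expect_identical(length(unique(model$assignment[1:n_per])), 1L)
    cs <- categorized_tables(model, lset)
    expect_identical(cs$codes[1],
                     model$code[model$assignment[["t01"]]])
  })
})
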