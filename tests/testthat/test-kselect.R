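make_blobs <- function(k, per = 20, d = 3, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    centers <- diag(1, k, d)   # unit-separated centers
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      matrix(stats::rnorm(per * d, sd = sd), per, d) +
        matrix(centers[j, ], per, d, byrow = TRUE)))
    list(x = x, truth = rep(seq_len(k), each = per))
  })
}

test_that("silhouette matches the hand-computed two-pair oracle", {
  x <- matrix(c(0, 0.2, 10, 10.2), ncol = 1)
  a <- c(1L, 1L, 2L, 2L)
  # per-point: s(0)=9.9/10.1, s(0.2)=9.7/9.9, symmetric for the other pair
  expect_equal(silhouette_score(x, a), (9.9 / 10.1 + 9.7 / 9.9) / 2)
})

test_that("silhouette conventions: singletons 0, single cluster errors", {
  x <- matrix(c(0, 5), ncol = 1)
  expect_identical(silhouette_score(x, c(1L, 2L)), 0)
  expect_error(silhouette_score(x, c(1L, 1L)), "at least 2")
  withr::with_seed(4, {
    # random labels on interleaved points give near-zero or negative scores
    xi <- matrix(seq(0, 1, length.out = 30), ncol = 1)
    ai <- sample(rep(1:2, 15))
    expect_lt(silhouette_score(xi, ai), 0.25)
    # silhouette is bounded
    for (i in 1:5) {
      xx <- matrix(stats::rnorm(40), 20, 2)
      aa <- sample(rep(1:4, 5))
      s <- silhouette_score(xx, aa)
      expect_gte(s, -1); expect_lte(s, 1)
    }
  })
})

test_that("gap rule selects k=1 for one blob and k=3 for three blobs", {
  one <- make_blobs(1, per = 40, d = 2, sd = 0.05, seed = 42)
  g1 <- gap_statistic(one$x, 1:4, B = 20, seed = 9)
  expect_identical(g1$k_hat, 1L)
  expect_true(all(is.finite(g1$gap)))
  three <- make_blobs(3, per = 20, d = 3, sd = 0.05, seed = 43)
  g3 <- gap_statistic(three$x, 1:6, B = 20, seed = 10)
  expect_identical(g3$k_hat, 3L)
  expect_error(gap_statistic(matrix(1, 5, 2), 1:3, B = 5, seed = 1),
               "degenerate")
})

test_that("the WCSS curve from the report is non-increasing in k", {
  blobs <- make_blobs(4, per = 15, d = 3, sd = 0.1, seed = 44)
  rep_ <- k_selection_report(blobs$x, 1:8, B = 5, seed = 12, n_init = 3)
  expect_true(all(diff(rep_$wcss) <= 1e-9))
  expect_true(all(rep_$silhouette[!is.na(rep_$silhouette)] >= -1 &
                  rep_$silhouette[!is.na(rep_$silhouette)] <= 1))
})

test_that("select_k takes the median vote, ties toward the smaller k", {
  fake <- function(votes) structure(
    list(k_grid = 1:8, votes = votes), class = "k_selection_report")
  expect_identical(select_k(fake(c(elbow = 5, gap = 5, silhouette = 5))), 5L)
  expect_identical(select_k(fake(c(elbow = 4, gap = 5, silhouette = 6))), 5L)
  expect_identical(select_k(fake(c(elbow = 4, gap = 6, silhouette = NA))), 4L)
  expect_error(select_k(structure(list(k_grid = 1:2, votes = NULL),
                                  class = "k_selection_report")),
               "at least 3")
})

test_that("select_k recovers the true k on a separated-blob benchmark", {
  blobs <- make_blobs(5, per = 15, d = 4, sd = 0.05, seed = 45)
  rep_ <- k_selection_report(blobs$x, 1:8, B = 10, seed = 13, n_init = 3)
  expect_identical(rep_$chosen_k, 5L)
})
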