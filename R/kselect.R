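# Cluster-count selection: elbow (WCSS curvature), gap statistic against
# uniform bounding-box references, and mean silhouette; combined by a
# median-of-three vote.

#' Gap statistic over a grid of k
#'
#' `gap(k) = mean_b log W*_kb - log W_k` with B reference datasets drawn
#' uniformly over the data's per-dimension bounding box;
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. The same seed-controlled
#' reference draws are reused across every k in the grid. The standard
#' selection rule picks the smallest k with `gap(k) >= gap(k+1) - s_{k+1}`.
#'
#' @param x numeric matrix of points.
#' @param k_grid increasing integer vector of candidate k.
#' @param B number of reference draws.
#' @param seed integer seed.
#' @param n_init restarts per k-means fit.
#' @param wcss_k optional precomputed observed WCSS per k (same order as
#'   `k_grid`); computed when missing.
#' @param weights optional per-point weights (observed fits only).
#' @return List with `gap`, `se` (both along `k_grid`), `k_hat` (the rule's
#'   choice) and `log_wk`.
#' @export
gap_statistic <- function(x, k_grid, B = 20L, seed = 1L, n_init = 5L,
                          wcss_k = NULL, weights = NULL) {
  x <- as.matrix(x)
  stopifnot(B >= 1)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (all(hi - lo == 0))
    stop("degenerate input: all points identical, gap statistic undefined")
  if (is.null(wcss_k))
    wcss_k <- vapply(seq_along(k_grid), function(i)
      kmeans_fit(x, k_grid[i], seed = seed + i, n_init = n_init,
                 weights = weights)$wcss, 0)
  refs <- local_seed(seed, {
    replicate(B, {
      m <- matrix(stats::runif(length(x)), nrow(x), ncol(x))
      sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
    }, simplify = FALSE)
  })
  logW_ref <- matrix(0, B, length(k_grid))
  for (b in seq_len(B)) {
    for (i in seq_along(k_grid)) {
      wkb <- kmeans_fit(refs[[b]], k_grid[i], seed = seed + 1000L * b + i,
                        n_init = n_init)$wcss
      logW_ref[b, i] <- log(max(wkb, 1e-300))
    }
  }
  gap <- colMeans(logW_ref) - log(pmax(wcss_k, 1e-300))
  se <- apply(logW_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  if (B == 1) se[] <- 0
  k_hat <- k_grid[length(k_grid)]
  for (i in seq_len(length(k_grid) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { k_hat <- k_grid[i]; break }
  }
  list(gap = gap, se = se, k_hat = k_hat,
       log_wk = log(pmax(wcss_k, 1e-300)))
}

#' Mean silhouette score
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance to the point's own
#' cluster and `b` the smallest mean distance to another cluster; points in
#' singleton clusters contribute 0.
#'
#' @param x numeric matrix of points.
#' @param assignment integer cluster per point (at least 2 clusters).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, assignment) {
  x <- as.matrix(x)
  ks <- sort(unique(assignment))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  sizes <- tabulate(assignment, max(ks))
  for (i in seq_len(n)) {
    own <- assignment[i]
    if (sizes[own] == 1) { s[i] <- 0; next }
    a <- sum(d[i, assignment == own]) / (sizes[own] - 1)
    b <- min(vapply(ks[ks != own], function(kk)
      mean(d[i, assignment == kk]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Compute the three k-selection curves over a grid
#'
#' Fits k-means for every k in the grid (warm-starting each k from the
#' previous fit so the best-of-restarts WCSS curve is non-increasing),
#' then computes the elbow, gap-statistic and silhouette criteria.
#'
#' @inheritParams gap_statistic
#' @param weights optional per-point weights.
#' @return Object of class `k_selection_report`: `k_grid`, `wcss`, `gap`,
#'   `se`, `silhouette`, per-criterion votes and `chosen_k` (see
#'   [select_k()]).
#' @export
k_selection_report <- function(x, k_grid, B = 20L, seed = 1L, n_init = 5L,
                               weights = NULL) {
  x <- as.matrix(x)
  k_grid <- as.integer(k_grid)
  stopifnot(!is.unsorted(k_grid), all(k_grid >= 1))
  if (length(k_grid) < 3) stop("k grid must have at least 3 candidates")
  fits <- vector("list", length(k_grid))
  wcss_k <- numeric(length(k_grid))
  sil <- rep(NA_real_, length(k_grid))
  prev <- NULL
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    warm <- NULL
    if (!is.null(prev) && k > nrow(prev$centroids)) {
      # split warm start: previous centroids plus the farthest points
      extra <- k - nrow(prev$centroids)
      d2 <- sq_dist_to(x, prev$centroids)
      own <- d2[cbind(seq_len(nrow(x)), prev$assignment)]
      far <- order(own, decreasing = TRUE)[seq_len(extra)]
      warm <- list(rbind(prev$centroids, x[far, , drop = FALSE]))
    }
    fits[[i]] <- kmeans_fit(x, k, seed = seed + i, n_init = n_init,
                            weights = weights, extra_init = warm)
    wcss_k[i] <- fits[[i]]$wcss
    if (k >= 2 && length(unique(fits[[i]]$assignment)) >= 2)
      sil[i] <- silhouette_score(x, fits[[i]]$assignment)
    prev <- fits[[i]]
  }
  gp <- gap_statistic(x, k_grid, B = B, seed = seed, n_init = n_init,
                      wcss_k = wcss_k, weights = weights)
  rep_ <- structure(list(k_grid = k_grid, wcss = wcss_k, gap = gp$gap,
                         se = gp$se, silhouette = sil, fits = fits,
                         votes = NULL, chosen_k = NULL),
                    class = "k_selection_report")
  rep_$votes <- k_votes(rep_, gap_k = gp$k_hat)
  rep_$chosen_k <- select_k(rep_)
  rep_
}

k_votes <- function(report, gap_k = NULL) {
  kg <- report$k_grid
  n <- length(kg)
  # elbow: max discrete curvature of the WCSS curve (interior points only)
  d2 <- report$wcss[1:(n - 2)] - 2 * report$wcss[2:(n - 1)] + report$wcss[3:n]
  elbow_k <- kg[which.max(d2) + 1L]
  if (is.null(gap_k)) {
    gap_k <- kg[n]
    for (i in seq_len(n - 1L)) {
      if (report$gap[i] >= report$gap[i + 1L] - report$se[i + 1L]) {
        gap_k <- kg[i]; break
      }
    }
  }
  sil_ok <- which(!is.na(report$silhouette))
  sil_k <- if (length(sil_ok) > 0)
    kg[sil_ok[which.max(report$silhouette[sil_ok])]] else NA_integer_
  c(elbow = elbow_k, gap = gap_k, silhouette = sil_k)
}

#' Combine the three k-selection criteria
#'
#' Elbow k is the maximum-curvature point of the WCSS curve (discrete second
#' difference), gap k follows the standard one-standard-error rule, and
#' silhouette k is the argmax of the mean silhouette. The chosen k is the
#' median of the three votes, ties toward the smaller k. The full report is
#' always available so callers can override (e.g. pin k to a known value).
#'
#' @param report a [k_selection_report()].
#' @return Integer chosen k.
#' @export
select_k <- function(report) {
  stopifnot(inherits(report, "k_selection_report"))
  if (length(report$k_grid) < 3) stop("k grid must have at least 3 candidates")
  votes <- report$votes %||% k_votes(report)
  votes <- votes[!is.na(votes)]
  sv <- sort(votes)
  as.integer(sv[ceiling(length(sv) / 2)])  # lower median: ties toward small k
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat("<k_selection_report> grid ", min(x$k_grid), "..", max(x$k_grid),
      "; votes: elbow=", x$votes[["elbow"]], " gap=", x$votes[["gap"]],
      " silhouette=", x$votes[["silhouette"]],
      "; chosen k = ", x$chosen_k, "\n", sep = "")
  invisible(x)
}
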