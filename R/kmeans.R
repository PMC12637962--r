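# K-means (Lloyd's algorithm, k-means++ initialization, restarts) with
# optional per-point weights. Written in-package rather than on top of
# stats::kmeans because the contract is specific: weighted points (label
# frequencies), deterministic seeding, empty-cluster repair by reseeding to
# the farthest point, and a warm-start hook that k-selection uses to keep the
# WCSS curve non-increasing in k.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

sq_dist_to <- function(x, centroids) {
  # n x k matrix of squared Euclidean distances
  xs <- rowSums(x^2)
  cs <- rowSums(centroids^2)
  d2 <- outer(xs, cs, "+") - 2 * x %*% t(centroids)
  pmax(d2, 0)
}

kmeanspp_init <- function(x, k, w) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1, prob = w)
  d2 <- sq_dist_to(x, x[idx[1], , drop = FALSE])[, 1]
  if (k > 1) for (j in 2:k) {
    p <- w * d2
    idx[j] <- if (sum(p) > 0) sample.int(n, 1, prob = p) else sample.int(n, 1)
    d2 <- pmin(d2, sq_dist_to(x, x[idx[j], , drop = FALSE])[, 1])
  }
  x[idx, , drop = FALSE]
}

lloyd <- function(x, centroids, w, tol, max_iter) {
  k <- nrow(centroids)
  n <- nrow(x)
  prev <- Inf
  assignment <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to(x, centroids)
    assignment <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed to the point farthest from its centroid
    repeat {
      sizes <- tabulate(assignment, k)
      empties <- which(sizes == 0)
      if (length(empties) == 0) break
      own <- d2[cbind(seq_len(n), assignment)]
      donor_pool <- which(tabulate(assignment, k)[assignment] > 1)
      far <- donor_pool[which.max(own[donor_pool])]
      assignment[far] <- empties[1]
      centroids[empties[1], ] <- x[far, ]
      d2[, empties[1]] <- sq_dist_to(x, x[far, , drop = FALSE])[, 1]
    }
    for (j in seq_len(k)) {
      sel <- assignment == j
      centroids[j, ] <- colSums(x[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    }
    cur <- wcss(x, assignment, centroids, w)
    if (prev - cur <= tol) break
    prev <- cur
  }
  list(centroids = centroids, assignment = assignment,
       wcss = wcss(x, assignment, centroids, w), iterations = it)
}

#' Fit k-means with k-means++ restarts
#'
#' Lloyd's algorithm, `n_init` k-means++ initializations, best
#' within-cluster sum of squares kept. Deterministic for a fixed `seed`.
#' Optional `weights` fit frequency-weighted k-means (each point counts as
#' `w` copies — used to cluster distinct labels by their observed counts).
#'
#' @param x numeric matrix (points in rows).
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param seed integer seed controlling all randomness.
#' @param n_init number of restarts.
#' @param tol convergence tolerance on the WCSS decrease.
#' @param max_iter Lloyd iteration cap per restart.
#' @param weights optional non-negative per-point weights.
#' @param extra_init optional list of centroid matrices used as additional
#'   (non-random) starts, e.g. warm starts from a smaller k.
#' @return List with `centroids` (k x d), `assignment` (length n, in 1..k),
#'   `wcss`, `iterations`.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_init = 10L, tol = 1e-10,
                       max_iter = 100L, weights = NULL, extra_init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  stopifnot(k >= 1)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  best <- NULL
  local_seed(seed, {
    starts <- c(replicate(n_init, kmeanspp_init(x, k, w), simplify = FALSE),
                extra_init %||% list())
    for (st in starts) {
      fit <- lloyd(x, st, w, tol, max_iter)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  best
}

#' Within-cluster sum of squares
#'
#' Sum over points of the squared Euclidean distance to the assigned
#' centroid (weighted when `weights` is given).
#'
#' @param x numeric matrix of points.
#' @param assignment integer cluster per point.
#' @param centroids centroid matrix.
#' @param weights optional per-point weights.
#' @return Non-negative scalar.
#' @export
wcss <- function(x, assignment, centroids, weights = NULL) {
  x <- as.matrix(x)
  w <- if (is.null(weights)) rep(1, nrow(x)) else as.numeric(weights)
  diff <- x - centroids[assignment, , drop = FALSE]
  sum(w * rowSums(diff^2))
}
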