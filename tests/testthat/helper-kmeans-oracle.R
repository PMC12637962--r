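# Exhaustive-partition oracle: the true optimum WCSS over every assignment
# of n points into k non-empty clusters (feasible for n <= 8).

best_partition_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 8)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < k) next
    cent <- matrix(0, k, ncol(x))
    for (j in seq_len(k)) cent[j, ] <- colMeans(x[a == j, , drop = FALSE])
    w <- sum((x - cent[a, , drop = FALSE])^2)
    if (w < best) best <- w
  }
  best
}
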