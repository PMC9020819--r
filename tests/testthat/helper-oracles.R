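# Independent brute-force oracles used across test files.

# O(n^2) pairwise-comparison rank oracle for percentile conversion:
# percentile_i = (#[x_j < x_i] + (#[x_j == x_i] - 1) / 2) / (n - 1)
brute_percentiles <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    (sum(x < x[i]) + (sum(x == x[i]) - 1) / 2) / (n - 1)
  }, 0)
}

# sort-and-partition reference for the 2-2-2 level split with the gap rule,
# written as explicit comparisons rather than vectorized ranking
brute_stratify <- function(p, min_gap = 0.1) {
  stopifnot(length(p) == 6L)
  ord <- order(p)
  lev <- character(6L)
  labels <- c("high", "high", "medium", "medium", "low", "low")
  for (pos in 1:6) lev[ord[pos]] <- labels[pos]
  s <- p[ord]
  if ((s[3] - s[2]) < min_gap) for (pos in 2:3) lev[ord[pos]] <- "excluded"
  if ((s[5] - s[4]) < min_gap) for (pos in 4:5) lev[ord[pos]] <- "excluded"
  lev
}

# naive double-loop windowed maximum (C1 spatial pooling oracle)
naive_max_pool <- function(M, ps, stride) {
  nr <- nrow(M) - ps + 1L; nc <- ncol(M) - ps + 1L
  ri <- seq(1L, nr, stride); ci <- seq(1L, nc, stride)
  out <- matrix(NA_real_, length(ri), length(ci))
  for (a in seq_along(ri)) for (b in seq_along(ci)) {
    best <- -Inf
    for (dr in 0:(ps - 1L)) for (dc in 0:(ps - 1L))
      best <- max(best, M[ri[a] + dr, ci[b] + dc])
    out[a, b] <- best
  }
  out
}
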