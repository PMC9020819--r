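#' Simulate arena arrangements for one observer
#'
#' Emulates the inverse-MDS task: for each category the observer's true
#' 4-point configuration is embedded in 2-D by classical scaling of its
#' pairwise distances, jittered with placement noise `sigma_place`, and
#' placed in a unit-radius arena. A single scale factor per observer maps
#' all categories into the arena, preserving the ordinal relations between
#' distances across categories (which the percentile pooling downstream
#' relies on).
#'
#' @param gt a `study_ground_truth`.
#' @param observer observer index.
#' @param sigma_place placement noise in arena units; defaults to the value
#'   stored in `gt`.
#' @return data.frame with columns `observer`, `category`, `exemplar`,
#'   `x`, `y` (arena units, centre origin, radius <= 1).
#' @export
simulate_arrangements <- function(gt, observer, sigma_place = gt$sigma_place) {
  cfg <- gt$config
  if (observer < 1L || observer > cfg$n_observers)
    stop("observer index out of range")
  set.seed(derive_seed(cfg$seed, "arrangement", observer))
  n_cat <- cfg$n_categories
  n_ex <- cfg$n_exemplars_per_category

  coords <- vector("list", n_cat)
  for (k in seq_len(n_cat)) {
    pts <- observer_points2d(gt, observer, k)
    D <- stats::dist(pts)
    X <- if (max(D) == 0) matrix(0, n_ex, 2L) else {
      emb <- suppressWarnings(stats::cmdscale(D, k = 2L))
      if (ncol(emb) < 2L) cbind(emb, 0)[, 1:2, drop = FALSE] else emb
    }
    coords[[k]] <- sweep(X, 2L, colMeans(X))
  }
  # common observer-wide scale: largest point radius maps to 0.8
  max_r <- max(vapply(coords, function(X) max(sqrt(rowSums(X^2)), 0), 0))
  s <- if (max_r > 0) 0.8 / max_r else 1
  out <- do.call(rbind, lapply(seq_len(n_cat), function(k) {
    X <- coords[[k]] * s
    if (sigma_place > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = sigma_place), nrow(X))
    r <- sqrt(rowSums(X^2))
    if (max(r) > 1) X <- X * (1 - 1e-9) / max(r)  # keep inside the arena
    data.frame(observer = observer, category = k, exemplar = seq_len(n_ex),
               x = X[, 1L], y = X[, 2L])
  }))
  rownames(out) <- NULL
  out
}
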