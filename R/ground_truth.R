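#' Generate the latent similarity structure of a simulated study
#'
#' Each category owns a 2-D exemplar configuration embedded in a
#' category-specific plane of a higher-dimensional latent space; the planes
#' differ across categories, so the full exemplar set spans the space. An
#' observer's perceived structure is the shared configuration plus an
#' in-plane perturbation of spread `sigma_observer`; the true perceived
#' distance for an observer is the Euclidean distance between their
#' perturbed exemplar points. Keeping each category's configuration planar
#' means a 2-D arena can express it without distortion, so noiseless
#' arrangements recover the true distance ranks exactly.
#'
#' Each exemplar additionally carries an intermediate visual-feature vector
#' standing for the image-level features a hierarchical Gabor model
#' extracts. These features describe objects at an intermediate level:
#' they follow the COARSE geometry (the subcluster centres), mixed with
#' feature structure unrelated to perceived similarity
#' (`alpha_intermediate` controls the mixing), plus a whisper of
#' exemplar-level jitter — so model distances track coarse perceived
#' structure but carry no fine-grained (within-twin) information, the way
#' intermediate-feature models distinguish dissimilar objects but not
#' highly similar exemplar pairs. Regions couple to them via
#' `w_intermediate`, and to the coarse geometry itself via `w_coarse`.
#'
#' @param config a [study_config()].
#' @param latent_dim dimensionality of the latent feature space.
#' @param sigma_observer spread of observer-specific perturbations of the
#'   subcluster centres (coarse idiosyncrasy: which kinds of exemplars an
#'   observer sees as more or less alike); 0 makes every observer's true
#'   structure identical.
#' @param sigma_observer_fine spread of observer-specific perturbations of
#'   individual exemplars (fine idiosyncrasy within twin pairs); scaled
#'   with `sigma_observer` by default so a shared-only cohort
#'   (`sigma_observer = 0`) has none.
#' @param sigma_place arena placement noise (arena units) used later by
#'   [simulate_arrangements()].
#' @param alpha_intermediate weight of the shared latent geometry inside the
#'   intermediate feature vectors, in `[0, 1]`.
#' @return object of class `study_ground_truth`.
#' @export
make_ground_truth <- function(config, latent_dim = 8L, sigma_observer = 1.8,
                              sigma_observer_fine = sigma_observer / 3,
                              sigma_place = 0.02,
                              alpha_intermediate = 0.1) {
  stopifnot(inherits(config, "study_config"))
  if (latent_dim < 2L) stop("latent_dim must be >= 2")
  if (sigma_observer < 0 || sigma_observer_fine < 0 || sigma_place < 0)
    stop("sigma parameters must be >= 0")
  n_cat <- config$n_categories
  n_ex <- config$n_exemplars_per_category
  n_obs <- config$n_observers

  set.seed(derive_seed(config$seed, "ground-truth"))
  categories <- vector("list", n_cat)
  intermediate <- array(0, dim = c(n_cat, n_ex, latent_dim))
  # exemplars come in close "twins" around spread-out subcluster centres, so
  # each category's 6 pairwise distances span a wide range and the
  # low/medium/high similarity levels are non-degenerate
  n_ctr <- max(2L, ceiling(n_ex / 2L))
  ctr_of <- rep(seq_len(n_ctr), each = 2L)[seq_len(n_ex)]
  for (k in seq_len(n_cat)) {
    # well-separated subcluster centres keep the coarse/fine scales distinct
    for (try in 1:100) {
      centres <- matrix(stats::rnorm(n_ctr * 2L, sd = 1.1), n_ctr, 2L)
      if (min(stats::dist(centres)) >= 1.2) break
    }
    twin_sd <- stats::runif(1L, 0.15, 0.4)  # fine-grain spacing varies by category
    jitter <- matrix(stats::rnorm(n_ex * 2L, sd = twin_sd), n_ex, 2L)
    shift <- colMeans(centres[ctr_of, , drop = FALSE] + jitter)
    scale_k <- stats::runif(1L, 0.8, 1.2)
    centres <- sweep(centres, 2L, shift) * scale_k
    base2d <- centres[ctr_of, , drop = FALSE] + jitter * scale_k
    basis <- qr.Q(qr(matrix(stats::rnorm(latent_dim * 2L), latent_dim, 2L)))
    # feature noise on a global scale so pure-noise features (alpha = 0) are
    # unrelated to any category's spread; centre-level noise keeps twin
    # exemplars nearly identical at the feature level
    eta_ctr <- matrix(stats::rnorm(n_ctr * latent_dim, sd = 0.5),
                      n_ctr, latent_dim)
    eta_ex <- matrix(stats::rnorm(n_ex * latent_dim, sd = 0.05),
                     n_ex, latent_dim)
    intermediate[k, , ] <-
      alpha_intermediate * (centres[ctr_of, , drop = FALSE] %*% t(basis)) +
      sqrt(1 - alpha_intermediate^2) * eta_ctr[ctr_of, , drop = FALSE] +
      eta_ex
    categories[[k]] <- list(base2d = base2d, basis = basis,
                            centres2d = centres, ctr_of = ctr_of)
  }
  # coarse offsets move whole twin clusters; fine offsets move exemplars.
  # With two subclusters the coarse offsets are constrained orthogonal to
  # the centre axis: observers then disagree (substantially) on how
  # dissimilar the coarse kinds are, but an observer's most similar pairs
  # remain the twin pairs, as in stimulus sets built around graded
  # similarity.
  ctr_off <- array(stats::rnorm(n_obs * n_cat * n_ctr * 2L,
                                sd = sigma_observer),
                   dim = c(n_obs, n_cat, n_ctr, 2L))
  ex_off <- array(stats::rnorm(n_obs * n_cat * n_ex * 2L,
                               sd = sigma_observer_fine),
                  dim = c(n_obs, n_cat, n_ex, 2L))
  if (n_ctr == 2L) {
    for (k in seq_len(n_cat)) {
      cc <- categories[[k]]$centres2d
      u <- (cc[2L, ] - cc[1L, ])
      u <- u / sqrt(sum(u^2))
      for (ci in 1:2) {
        proj <- ctr_off[, k, ci, 1L] * u[1L] + ctr_off[, k, ci, 2L] * u[2L]
        ctr_off[, k, ci, 1L] <- ctr_off[, k, ci, 1L] - proj * u[1L]
        ctr_off[, k, ci, 2L] <- ctr_off[, k, ci, 2L] - proj * u[2L]
      }
    }
  }
  offsets <- array(0, dim = c(n_obs, n_cat, n_ex, 2L))
  for (e in seq_len(n_ex))
    offsets[, , e, ] <- ctr_off[, , ctr_of[e], ] + ex_off[, , e, ]
  if (sigma_observer == 0 && sigma_observer_fine == 0) offsets[] <- 0

  # graded-similarity guarantee: in every observer's geometry (and in the
  # shared one) each twin pair stays clearly closer than any cross-cluster
  # pair, so the fine and coarse similarity scales never swap
  for (k in seq_len(n_cat)) {
    categories[[k]]$base2d <- cap_twin_distances(categories[[k]]$base2d,
                                                 ctr_of)
    for (o in seq_len(n_obs)) {
      pts <- categories[[k]]$base2d + offsets[o, k, , ]
      offsets[o, k, , ] <- cap_twin_distances(pts, ctr_of) -
        categories[[k]]$base2d
    }
  }

  structure(list(config = config, latent_dim = as.integer(latent_dim),
                 sigma_observer = sigma_observer,
                 sigma_observer_fine = sigma_observer_fine,
                 sigma_place = sigma_place,
                 alpha_intermediate = alpha_intermediate,
                 categories = categories, offsets = offsets,
                 intermediate = intermediate),
            class = "study_ground_truth")
}

# Shrink twin-pair separations that rival the smallest cross-cluster
# distance: both members move toward their pair midpoint until the pair is
# at most `factor` times the closest cross-pair distance.
cap_twin_distances <- function(pts, ctr_of, factor = 0.8) {
  n <- nrow(pts)
  same <- outer(ctr_of, ctr_of, "==")
  D <- as.matrix(stats::dist(pts))
  cross <- D[!same & upper.tri(D)]
  if (!length(cross)) return(pts)
  cap <- factor * min(cross)
  m <- 0L  # successively smaller caps keep capped pairs distinct (no ties)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (same[i, j] && D[i, j] > cap * (1 - 0.07 * m) && D[i, j] > 0) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      sc <- cap * (1 - 0.07 * m) / D[i, j]
      pts[i, ] <- mid + (pts[i, ] - mid) * sc
      pts[j, ] <- mid + (pts[j, ] - mid) * sc
      m <- m + 1L
    }
  }
  pts
}

# Observer's perceived 2-D exemplar points for one category.
observer_points2d <- function(gt, observer, category) {
  gt$categories[[category]]$base2d + gt$offsets[observer, category, , ]
}

# Observer's exemplar coordinates in the full latent space (n_ex x latent_dim).
observer_latent <- function(gt, observer, category) {
  cc <- gt$categories[[category]]
  (cc$base2d + gt$offsets[observer, category, , ]) %*% t(cc$basis)
}

# Shared (offset-free) latent coordinates.
shared_latent <- function(gt, category) {
  cc <- gt$categories[[category]]
  cc$base2d %*% t(cc$basis)
}

# Coarse shared coordinates: every exemplar sits at its subcluster centre,
# so twin exemplars are indistinguishable at this level of description.
coarse_latent <- function(gt, category) {
  cc <- gt$categories[[category]]
  cc$centres2d[cc$ctr_of, , drop = FALSE] %*% t(cc$basis)
}

#' True perceived within-category distances for one observer
#'
#' @param gt a `study_ground_truth`.
#' @param observer observer index.
#' @return data.frame with columns `category`, `i`, `j`, `distance`.
#' @export
true_distances <- function(gt, observer) {
  cfg <- gt$config
  pairs <- pair_table(cfg$n_exemplars_per_category)
  out <- do.call(rbind, lapply(seq_len(cfg$n_categories), function(k) {
    pts <- observer_points2d(gt, observer, k)
    d <- sqrt(rowSums((pts[pairs$i, , drop = FALSE] -
                         pts[pairs$j, , drop = FALSE])^2))
    data.frame(category = k, i = pairs$i, j = pairs$j, distance = d)
  }))
  rownames(out) <- NULL
  out
}

#' RDM of the ground-truth intermediate feature vectors
#'
#' Within-category Euclidean distances between the intermediate
#' visual-feature vectors, percentile-converted with the shared convention.
#' Serves as the model RDM a simulated intermediate-feature region should
#' correlate with.
#'
#' @param gt a `study_ground_truth`.
#' @return RDM data.frame (`category`, `i`, `j`, `raw`, `percentile`).
#' @export
intermediate_feature_rdm <- function(gt) {
  cfg <- gt$config
  pairs <- pair_table(cfg$n_exemplars_per_category)
  out <- do.call(rbind, lapply(seq_len(cfg$n_categories), function(k) {
    f <- gt$intermediate[k, , ]
    d <- sqrt(rowSums((f[pairs$i, , drop = FALSE] -
                         f[pairs$j, , drop = FALSE])^2))
    data.frame(category = k, i = pairs$i, j = pairs$j, raw = d)
  }))
  out$percentile <- to_percentiles(out$raw)
  rownames(out) <- NULL
  out
}
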