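#' Gabor filter bank for the S1 layer
#'
#' Oriented Gabor filters at several sizes, modelling V1 simple cells.
#' Filter parameters follow the standard size-dependent schedule
#' (sigma = 0.0036 s^2 + 0.35 s + 0.18, wavelength sigma / 0.8, aspect
#' 0.3); each filter is restricted to a circular aperture, zero-meaned and
#' scaled to unit norm.
#'
#' @param n_orientations number of equally spaced orientations.
#' @param sizes odd filter sizes in pixels, in increasing order; grouped in
#'   pairs into scale bands by [c1_pool()].
#' @return object of class `gabor_bank`.
#' @export
gabor_bank <- function(n_orientations = 4L, sizes = seq(7L, 21L, 2L)) {
  if (any(sizes %% 2L == 0L)) stop("filter sizes must be odd")
  thetas <- pi * (seq_len(n_orientations) - 1L) / n_orientations
  filters <- lapply(sizes, function(s) {
    sigma <- 0.0036 * s^2 + 0.35 * s + 0.18
    lambda <- sigma / 0.8
    half <- (s - 1L) / 2L
    g <- expand.grid(x = -half:half, y = -half:half)
    lapply(thetas, function(th) {
      x0 <- g$x * cos(th) + g$y * sin(th)
      y0 <- -g$x * sin(th) + g$y * cos(th)
      f <- exp(-(x0^2 + 0.3^2 * y0^2) / (2 * sigma^2)) *
        cos(2 * pi * x0 / lambda)
      f[g$x^2 + g$y^2 > half^2] <- 0
      f <- f - mean(f)
      f <- f / sqrt(sum(f^2))
      matrix(f, s, s)
    })
  })
  structure(list(n_orientations = as.integer(n_orientations),
                 sizes = as.integer(sizes), thetas = thetas,
                 filters = filters),
            class = "gabor_bank")
}

# valid-shape 2-D cross-correlation via FFT (kernel NOT flipped)
xcorr2_valid <- function(A, K) {
  na <- dim(A); nk <- dim(K)
  if (any(nk > na)) stop("kernel larger than image")
  n <- na + nk - 1L
  Ap <- matrix(0, n[1L], n[2L]); Ap[seq_len(na[1L]), seq_len(na[2L])] <- A
  Kp <- matrix(0, n[1L], n[2L])
  Kp[seq_len(nk[1L]), seq_len(nk[2L])] <- K[nk[1L]:1L, nk[2L]:1L]
  full <- Re(stats::fft(stats::fft(Ap) * stats::fft(Kp), inverse = TRUE)) /
    prod(n)
  full[nk[1L]:na[1L], nk[2L]:na[2L], drop = FALSE]
}

#' S1 layer: normalized Gabor responses
#'
#' Applies every filter of the bank to a grayscale image using normalized
#' cross-correlation: the absolute filter response in each window divided
#' by the window's centred norm, making responses invariant to global
#' affine intensity changes. Maps follow the valid-convolution convention.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param bank a [gabor_bank()].
#' @return list (per size) of lists (per orientation) of response maps.
#' @export
s1_apply <- function(image, bank) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must be normalized to [0, 1]")
  if (min(dim(image)) < max(bank$sizes))
    stop("image smaller than the largest filter (", max(bank$sizes), " px)")
  lapply(seq_along(bank$sizes), function(si) {
    s <- bank$sizes[si]
    ones <- matrix(1, s, s)
    win_sum <- xcorr2_valid(image, ones)
    win_ss <- xcorr2_valid(image^2, ones)
    cnorm <- sqrt(pmax(win_ss - win_sum^2 / (s * s), 0))
    lapply(bank$filters[[si]], function(f) {
      num <- abs(xcorr2_valid(image, f))
      out <- num / cnorm
      out[cnorm < 1e-6] <- 0  # flat windows (tolerates FFT round-off)
      out
    })
  })
}

# vectorized windowed max over ps x ps windows with the given stride
spatial_max_pool <- function(M, ps, stride) {
  nr <- nrow(M) - ps + 1L; nc <- ncol(M) - ps + 1L
  if (nr < 1L || nc < 1L) return(matrix(numeric(0), 0L, 0L))
  ri <- seq(1L, nr, stride); ci <- seq(1L, nc, stride)
  out <- matrix(-Inf, length(ri), length(ci))
  for (dr in 0:(ps - 1L)) for (dc in 0:(ps - 1L))
    out <- pmax(out, M[ri + dr, ci + dc, drop = FALSE])
  out
}

center_crop <- function(M, dims) {
  r0 <- (nrow(M) - dims[1L]) %/% 2L
  c0 <- (ncol(M) - dims[2L]) %/% 2L
  M[r0 + seq_len(dims[1L]), c0 + seq_len(dims[2L]), drop = FALSE]
}

#' C1 layer: complex-cell pooling
#'
#' Pools S1 responses with a local spatial maximum (window `pool_size`,
#' stride half the window) and a maximum over the adjacent filter sizes of
#' each scale band, per orientation — conferring tolerance to small shifts
#' and scale changes.
#'
#' @param s1 output of [s1_apply()].
#' @param bank the bank that produced it.
#' @param pool_sizes spatial pooling window per band; defaults to
#'   8, 10, 12, ... in band order.
#' @return list (per band) of lists (per orientation) of C1 maps.
#' @export
c1_pool <- function(s1, bank, pool_sizes = NULL) {
  n_bands <- length(bank$sizes) %/% 2L
  if (n_bands < 1L) stop("bank needs at least 2 sizes to form a band")
  if (is.null(pool_sizes)) pool_sizes <- 8L + 2L * (seq_len(n_bands) - 1L)
  lapply(seq_len(n_bands), function(b) {
    si <- c(2L * b - 1L, 2L * b)
    ps <- pool_sizes[b]
    lapply(seq_len(bank$n_orientations), function(oi) {
      maps <- lapply(si, function(s) s1[[s]][[oi]])
      dims <- c(min(vapply(maps, nrow, 0L)), min(vapply(maps, ncol, 0L)))
      merged <- Reduce(pmax, lapply(maps, center_crop, dims = dims))
      spatial_max_pool(merged, ps, max(1L, ps %/% 2L))
    })
  })
}

#' Sample an S2 patch dictionary from C1 maps
#'
#' Draws `n_patches` multi-orientation patches at random images, bands and
#' positions; each patch is the local C1 activity across all orientations
#' and serves as an S2 prototype.
#'
#' @param c1_list list of C1 structures (one per image, from [c1_pool()]).
#' @param n_patches dictionary size.
#' @param patch_sizes candidate square patch sizes in C1 units.
#' @param seed RNG seed.
#' @return object of class `s2_dictionary`.
#' @export
build_dictionary <- function(c1_list, n_patches = 200L,
                             patch_sizes = c(4L, 8L, 12L), seed = 1L) {
  if (n_patches < 1L) stop("n_patches must be >= 1")
  set.seed(derive_seed(seed, "s2-dictionary"))
  n_orient <- length(c1_list[[1L]][[1L]])
  patches <- vector("list", n_patches)
  for (pi in seq_len(n_patches)) {
    for (attempt in 1:100) {
      img <- sample(length(c1_list), 1L)
      band <- sample(length(c1_list[[img]]), 1L)
      p <- sample(patch_sizes, 1L)
      m <- c1_list[[img]][[band]][[1L]]
      if (nrow(m) >= p && ncol(m) >= p) break
      if (attempt == 100L)
        stop("no C1 map large enough for any requested patch size")
    }
    r <- sample(nrow(m) - p + 1L, 1L); cc <- sample(ncol(m) - p + 1L, 1L)
    patches[[pi]] <- array(
      vapply(seq_len(n_orient), function(oi)
        c1_list[[img]][[band]][[oi]][r + 0:(p - 1L), cc + 0:(p - 1L)],
        matrix(0, p, p)),
      dim = c(p, p, n_orient))
  }
  structure(list(patches = patches, n_orientations = n_orient,
                 patch_sizes = patch_sizes, seed = seed),
            class = "s2_dictionary")
}

#' C2 features of an image
#'
#' S2 units compare every C1 window (across all orientations) of every
#' scale band with each dictionary patch through a Gaussian radial-basis
#' function of their Euclidean distance (normalized per patch element); the
#' C2 value of a patch is the global maximum over positions and bands, so
#' features are tolerant to translation and scale. Values lie in (0, 1],
#' reaching 1 only on an exact patch match.
#'
#' @param c1 one image's C1 structure.
#' @param dict an [build_dictionary()] dictionary.
#' @param sigma_rbf radial-basis width (per normalized element).
#' @return numeric C2 vector, one value per dictionary patch.
#' @export
c2_features <- function(c1, dict, sigma_rbf = 1) {
  vapply(dict$patches, function(P) {
    p <- dim(P)[1L]
    npix <- length(P)
    best <- -Inf
    for (band in seq_along(c1)) {
      m1 <- c1[[band]][[1L]]
      if (nrow(m1) < p || ncol(m1) < p) next
      ones <- matrix(1, p, p)
      d2 <- 0
      for (oi in seq_len(dict$n_orientations)) {
        M <- c1[[band]][[oi]]
        d2 <- d2 + xcorr2_valid(M^2, ones) -
          2 * xcorr2_valid(M, P[, , oi]) + sum(P[, , oi]^2)
      }
      best <- max(best, max(-pmax(d2, 0)))
    }
    if (!is.finite(best))
      stop("no C1 map large enough for a dictionary patch")
    exp(best / (2 * sigma_rbf^2 * npix))
  }, 0)
}

#' Model RDM from C2 features of a stimulus set
#'
#' Runs the full S1 -> C1 -> S2/C2 hierarchy on one grayscale image per
#' exemplar, then builds the within-category model RDM as 1 - Pearson r
#' between C2 vectors, percentile-converted with the shared convention.
#'
#' @param images list of grayscale image matrices, one per exemplar.
#' @param ids data.frame with `category` and `exemplar` per image.
#' @param bank a [gabor_bank()].
#' @param dict an existing dictionary, or `NULL` to sample one from these
#'   images.
#' @param n_patches,patch_sizes,seed dictionary parameters when `dict` is
#'   `NULL`.
#' @return list with `rdm` (RDM data.frame), `c2` (images x patches
#'   matrix) and `dict`.
#' @export
hmax_rdm <- function(images, ids, bank = gabor_bank(), dict = NULL,
                     n_patches = 200L, patch_sizes = c(4L, 8L, 12L),
                     seed = 1L) {
  if (length(images) != nrow(ids))
    stop("need one image per (category, exemplar) row")
  full <- expand.grid(exemplar = sort(unique(ids$exemplar)),
                      category = sort(unique(ids$category)))
  missing <- !paste(full$category, full$exemplar) %in%
    paste(ids$category, ids$exemplar)
  if (any(missing))
    stop("missing image for exemplar(s): ",
         paste(paste(full$category, full$exemplar)[missing], collapse = "; "))
  c1_list <- lapply(images, function(im) c1_pool(s1_apply(im, bank), bank))
  if (is.null(dict))
    dict <- build_dictionary(c1_list, n_patches = n_patches,
                             patch_sizes = patch_sizes, seed = seed)
  C2 <- t(vapply(c1_list, c2_features, numeric(length(dict$patches)),
                 dict = dict))
  out <- do.call(rbind, lapply(sort(unique(ids$category)), function(k) {
    rows <- which(ids$category == k)
    rows <- rows[order(ids$exemplar[rows])]
    pairs <- pair_table(length(rows))
    d <- vapply(seq_len(nrow(pairs)), function(pi)
      1 - stats::cor(C2[rows[pairs$i[pi]], ], C2[rows[pairs$j[pi]], ]), 0)
    data.frame(category = k, i = ids$exemplar[rows][pairs$i],
               j = ids$exemplar[rows][pairs$j], raw = d)
  }))
  out$percentile <- to_percentiles(out$raw)
  list(rdm = rdm_sort(out), c2 = C2, dict = dict)
}

#' Procedural texture stimuli for model tests
#'
#' Generates one grayscale image per exemplar: each category owns a
#' prototype mixture of oriented sinusoidal components, and exemplars
#' jitter its orientations, frequencies and phases. These are synthetic
#' stand-ins for object photographs, sufficient to exercise the model
#' hierarchy.
#'
#' @param n_categories,n_exemplars stimulus set design.
#' @param size image side in pixels.
#' @param jitter exemplar-level parameter jitter (fraction of prototype).
#' @param seed RNG seed.
#' @return list with `images` (list of matrices in `[0, 1]`) and `ids`
#'   (data.frame `category`, `exemplar`).
#' @export
generate_stimulus_images <- function(n_categories = 10L, n_exemplars = 4L,
                                     size = 64L, jitter = 0.15, seed = 1L) {
  set.seed(derive_seed(seed, "stimuli"))
  g <- expand.grid(x = seq_len(size), y = seq_len(size))
  images <- list(); ids <- NULL
  for (k in seq_len(n_categories)) {
    n_comp <- 3L
    th0 <- stats::runif(n_comp, 0, pi)
    fr0 <- stats::runif(n_comp, 0.05, 0.25)
    amp <- stats::runif(n_comp, 0.5, 1)
    for (e in seq_len(n_exemplars)) {
      th <- th0 + stats::rnorm(n_comp, sd = jitter)
      fr <- fr0 * (1 + stats::rnorm(n_comp, sd = jitter))
      ph <- stats::runif(n_comp, 0, 2 * pi)
      im <- 0
      for (ci in seq_len(n_comp))
        im <- im + amp[ci] * sin(2 * pi * fr[ci] *
                                   (g$x * cos(th[ci]) + g$y * sin(th[ci])) +
                                   ph[ci])
      im <- matrix(im, size, size)
      im <- (im - min(im)) / (max(im) - min(im))
      images[[length(images) + 1L]] <- im
      ids <- rbind(ids, data.frame(category = k, exemplar = e))
    }
  }
  list(images = images, ids = ids)
}
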