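small_bank <- function() gabor_bank(n_orientations = 4, sizes = c(7, 9, 11, 13))

grating <- function(size, theta, freq = 0.2) {
  g <- expand.grid(x = seq_len(size), y = seq_len(size))
  im <- sin(2 * pi * freq * (g$x * cos(theta) + g$y * sin(theta)))
  matrix((im + 1) / 2, size, size)
}

test_that("gabor filters are zero-mean and unit-norm", {
  bank <- small_bank()
  for (fs in bank$filters) for (f in fs) {
    expect_lt(abs(sum(f)), 1e-10)
    expect_equal(sum(f^2), 1)
  }
})

test_that("S1 responds to orientation and ignores flat images", {
  bank <- small_bank()
  flat <- matrix(0.5, 32, 32)
  s1 <- s1_apply(flat, bank)
  expect_equal(max(abs(unlist(s1))), 0)
  vert <- grating(32, 0)          # varies along x
  s1v <- s1_apply(vert, bank)
  resp <- vapply(1:4, function(oi) mean(s1v[[2]][[oi]]), 0)
  expect_equal(which.max(resp), 1L)   # orientation 0 dominates
  expect_error(s1_apply(matrix(0.5, 5, 5), bank), "smaller than")
  expect_error(s1_apply(matrix(2, 32, 32), bank), "normalized")
})

test_that("S1 is invariant to global affine intensity changes", {
  bank <- small_bank()
  set.seed(2)
  im <- matrix(runif(32 * 32), 32, 32)
  s1 <- s1_apply(im, bank)
  s1b <- s1_apply(0.5 * im + 0.25, bank)
  expect_equal(unlist(s1b), unlist(s1), tolerance = 1e-8)
})

test_that("C1 pooling matches the naive windowed-max oracle", {
  bank <- small_bank()
  set.seed(3)
  im <- matrix(runif(32 * 32), 32, 32)
  s1 <- s1_apply(im, bank)
  c1 <- c1_pool(s1, bank)
  for (b in 1:2) for (oi in 1:4) {
    maps <- lapply(c(2 * b - 1, 2 * b), function(s) s1[[s]][[oi]])
    dims <- c(min(vapply(maps, nrow, 0L)), min(vapply(maps, ncol, 0L)))
    crop <- lapply(maps, function(M) {
      r0 <- (nrow(M) - dims[1]) %/% 2; c0 <- (ncol(M) - dims[2]) %/% 2
      M[r0 + seq_len(dims[1]), c0 + seq_len(dims[2]), drop = FALSE]
    })
    merged <- pmax(crop[[1]], crop[[2]])
    ps <- c(8L, 10L)[b]
    expect_equal(c1[[b]][[oi]], naive_max_pool(merged, ps, ps %/% 2L))
  }
})

test_that("C1 tolerates small translations", {
  bank <- small_bank()
  set.seed(4)
  base <- matrix(0, 48, 48)
  base[20:28, 20:28] <- matrix(runif(81), 9, 9)
  c1a <- c1_pool(s1_apply(base, bank), bank)
  shifted <- matrix(0, 48, 48)
  shifted[21:29, 21:29] <- base[20:28, 20:28]
  c1b <- c1_pool(s1_apply(shifted, bank), bank)
  # pooled representation nearly unchanged under a 1-px shift
  expect_gt(stats::cor(unlist(c1a), unlist(c1b)), 0.85)
})

test_that("C2 features are bounded, deterministic and peak on exact patches", {
  bank <- small_bank()
  stim <- generate_stimulus_images(n_categories = 3, n_exemplars = 2,
                                   size = 48, seed = 5)
  c1_list <- lapply(stim$images, function(im) c1_pool(s1_apply(im, bank), bank))
  dict <- build_dictionary(c1_list, n_patches = 12, patch_sizes = c(4, 6),
                           seed = 9)
  dict2 <- build_dictionary(c1_list, n_patches = 12, patch_sizes = c(4, 6),
                            seed = 9)
  expect_identical(dict$patches, dict2$patches)
  c2 <- c2_features(c1_list[[1]], dict)
  expect_length(c2, 12L)
  expect_true(all(c2 > 0 & c2 <= 1))
  expect_identical(c2, c2_features(c1_list[[1]], dict))
  # dictionary sampled from these images: some patch matches its source
  all_c2 <- vapply(c1_list, c2_features, numeric(12), dict = dict)
  expect_equal(max(all_c2), 1, tolerance = 1e-6)
  # duplicate images give identical features
  expect_identical(c2_features(c1_list[[1]], dict), c2)
  d1 <- build_dictionary(c1_list, n_patches = 1, patch_sizes = 4, seed = 2)
  expect_length(c2_features(c1_list[[2]], d1), 1L)
})

test_that("the model RDM has the within-category support and round-trips", {
  bank <- small_bank()
  stim <- generate_stimulus_images(n_categories = 4, n_exemplars = 4,
                                   size = 48, seed = 6)
  res <- hmax_rdm(stim$images, stim$ids, bank = bank, n_patches = 20,
                  patch_sizes = c(4, 6), seed = 3)
  expect_equal(nrow(res$rdm), 4L * 6L)
  expect_equal(res$rdm$percentile, to_percentiles(res$rdm$raw))
  # recompute dissimilarities from the saved C2 matrix (round-trip oracle)
  for (k in 1:4) {
    rows <- which(stim$ids$category == k)
    pairs <- pair_table(4)
    manual <- vapply(seq_len(nrow(pairs)), function(pi)
      1 - stats::cor(res$c2[rows[pairs$i[pi]], ],
                     res$c2[rows[pairs$j[pi]], ]), 0)
    expect_equal(res$rdm$raw[res$rdm$category == k], manual)
  }
  expect_error(hmax_rdm(stim$images[-1], stim$ids[-1, ], bank = bank),
               "missing image")
  # identical images at matched positions yield zero dissimilarity
  ims <- stim$images
  ims[[2]] <- ims[[1]]
  res2 <- hmax_rdm(ims, stim$ids, bank = bank, dict = res$dict)
  expect_equal(res2$rdm$raw[res2$rdm$category == 1 & res2$rdm$i == 1 &
                              res2$rdm$j == 2], 0, tolerance = 1e-10)
})
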