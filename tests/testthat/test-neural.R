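make_pattern_set <- function(n_runs = 4L, n_voxels = 20L, seed = 42L,
                             region = NULL) {
  cfg <- small_config(n_runs = n_runs, seed = seed)
  gt <- make_ground_truth(cfg)
  tr <- generate_trial_sequence(cfg, seed = seed)
  if (is.null(region))
    region <- region_spec("signal", n_voxels = n_voxels, w_observer = 1,
                          sigma_noise = 1)
  list(ps = simulate_voxel_patterns(gt, 1, region, tr), gt = gt, trials = tr,
       cfg = cfg)
}

test_that("exemplar means aggregate exactly the no-response trials", {
  x <- make_pattern_set()
  em <- exemplar_mean_patterns(x$ps)
  expect_equal(nrow(em$means), 40L)
  expect_true(all(em$n_trials ==
                    x$cfg$reps_noresponse_per_run * x$cfg$n_runs))
  # single-trial subset: the mean is that trial's pattern
  t1 <- which(x$ps$index$trial_type == "no_response" &
                x$ps$index$run == 1 & x$ps$index$category == 1 &
                x$ps$index$exemplar == 1)
  em1 <- exemplar_mean_patterns(x$ps, run_subset = 1)
  manual <- colMeans(x$ps$patterns[t1, , drop = FALSE])
  expect_equal(em1$means[1, ], manual, ignore_attr = TRUE)
  expect_error(exemplar_mean_patterns(x$ps, run_subset = 99),
               "no qualifying")
})

test_that("exemplar means converge to the signal as trials accumulate", {
  x <- make_pattern_set(n_runs = 8L)
  # same region name and seed: identical read-out and baseline, noise-free
  clean <- simulate_voxel_patterns(
    x$gt, 1, region_spec("signal", n_voxels = 20, w_observer = 1,
                         sigma_noise = 0), x$trials)
  em_noisy <- exemplar_mean_patterns(x$ps)
  em_clean <- exemplar_mean_patterns(clean)
  # noise sd 1 over 24 trials: mean error per voxel ~ N(0, 1/24)
  err <- em_noisy$means - em_clean$means
  expect_lt(mean(err^2), 3 / 24)
  expect_gt(mean(err^2), 1 / (3 * 24))
})

test_that("brain RDM encodes 1 - Pearson r with the shared percentile pooling", {
  means <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8),      # r = 1 -> d = 0
                 c(1, -1, 1, -1), c(1, 1, -1, -1),  # orthogonal -> d = 1
                 matrix(rnorm(4), 1))
  em <- list(means = rbind(means, matrix(rnorm(4 * 19), 19)),
             index = data.frame(category = rep(1:6, each = 4),
                                exemplar = rep(1:4, 6)))
  rdm <- build_brain_rdm(em)
  expect_equal(rdm$raw[rdm$category == 1 & rdm$i == 1 & rdm$j == 2], 0)
  expect_equal(rdm$raw[rdm$category == 1 & rdm$i == 3 & rdm$j == 4], 1)
  expect_equal(nrow(rdm), 36L)
  expect_equal(rdm$percentile, to_percentiles(rdm$raw))
  em$means[3, ] <- 5  # zero-variance pattern
  expect_error(build_brain_rdm(em), "zero-variance")
})

test_that("brain RDM is invariant to voxel permutation and pattern offsets", {
  x <- make_pattern_set()
  em <- exemplar_mean_patterns(x$ps)
  rdm <- build_brain_rdm(em)
  em_perm <- em; em_perm$means <- em$means[, sample(ncol(em$means))]
  expect_equal(build_brain_rdm(em_perm)$raw, rdm$raw)
  em_off <- em; em_off$means <- em$means + 7.5
  expect_equal(build_brain_rdm(em_off)$raw, rdm$raw, tolerance = 1e-10)
})

test_that("brain RDM percentiles are invariant to monotone transforms of 1 - r", {
  x <- make_pattern_set()
  rdm <- build_brain_rdm(exemplar_mean_patterns(x$ps))
  expect_equal(to_percentiles(rdm$raw^2), rdm$percentile)  # raw in [0, 2] > 0
})

test_that("split-half stability separates signal from noise regions", {
  x <- make_pattern_set(n_runs = 8L,
                        region = region_spec("clean", n_voxels = 20,
                                             w_observer = 1,
                                             sigma_noise = 0))
  expect_equal(split_half_stability(x$ps), 1)
  noise_r <- vapply(1:8, function(s) {
    y <- make_pattern_set(n_runs = 4L, seed = 100 + s,
                          region = region_spec("noise", n_voxels = 20,
                                               sigma_noise = 1))
    split_half_stability(y$ps)
  }, 0)
  expect_lt(abs(mean(noise_r)), 0.2)
  sig_r <- split_half_stability(x$ps)
  mid <- make_pattern_set(n_runs = 8L,
                          region = region_spec("mid", n_voxels = 20,
                                               w_observer = 1,
                                               sigma_noise = 3))
  expect_gt(sig_r, split_half_stability(mid$ps))
})
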