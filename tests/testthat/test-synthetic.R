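test_that("ground truth is reproducible and respects the observer knob", {
  cfg <- small_config()
  gt1 <- make_ground_truth(cfg)
  gt2 <- make_ground_truth(cfg)
  expect_identical(gt1$categories, gt2$categories)
  expect_identical(gt1$offsets, gt2$offsets)

  gt0 <- make_ground_truth(cfg, sigma_observer = 0)
  d1 <- true_distances(gt0, 1)$distance
  for (o in 2:cfg$n_observers)
    expect_equal(true_distances(gt0, o)$distance, d1)

  expect_error(make_ground_truth(cfg, sigma_observer = -1), ">= 0")
  expect_error(study_config(n_categories = 0), ">= 1")
})

test_that("observer perturbations yield intermediate intersubject agreement", {
  # computed on the generated true structures directly, before any pipeline
  cfg <- study_config(n_observers = 10, seed = 5)
  gt <- make_ground_truth(cfg, sigma_observer = 0.5)
  D <- vapply(1:10, function(o) true_distances(gt, o)$distance, numeric(60))
  loo_r <- vapply(1:10, function(o)
    stats::cor(D[, o], rowMeans(D[, -o])), 0)
  expect_true(mean(loo_r) > 0 && mean(loo_r) < 1)
})

test_that("noiseless arrangements embed the true distances exactly", {
  cfg <- small_config()
  gt <- make_ground_truth(cfg, sigma_place = 0)
  for (o in c(1L, 3L)) {
    arr <- simulate_arrangements(gt, o, sigma_place = 0)
    rdm <- build_behaviour_rdm(arr)
    td <- true_distances(gt, o)
    expect_equal(stats::cor(rdm$raw, td$distance, method = "spearman"), 1)
    # common scale: raw distances proportional to true distances
    expect_lt(stats::sd(rdm$raw / td$distance), 1e-8)
  }
})

test_that("arrangement coordinates stay inside the unit arena", {
  st <- small_behaviour_cohort()
  r <- sqrt(st$arrangements$x^2 + st$arrangements$y^2)
  expect_true(all(r <= 1 + 1e-9))
})

test_that("distinct observers produce distinct arrangement RDMs", {
  st <- small_behaviour_cohort()
  rdms <- behaviour_rdms_of(st)
  expect_gt(sum(abs(rdms[[1]]$raw - rdms[[2]]$raw)), 0.01)
})

test_that("behaviour simulation couples errors to own perceived similarity", {
  cfg <- small_config(n_runs = 8L)
  gt <- make_ground_truth(cfg)
  tr <- generate_trial_sequence(cfg, seed = 9)
  # null slope: confusion probability flat in similarity
  log0 <- simulate_behaviour(gt, 1, tr,
                             params = behaviour_params(error_slope = 0),
                             seed = 21)
  sc0 <- score_oneback(log0, tr)
  part <- stratify_levels(build_behaviour_rdm(simulate_arrangements(gt, 1)))
  perf0 <- performance_by_level(sc0, part)
  s0 <- similarity_slope(perf0, "error")
  log1 <- simulate_behaviour(gt, 1, tr, seed = 21)
  s1 <- similarity_slope(performance_by_level(score_oneback(log1, tr), part),
                         "error")
  expect_lt(abs(s0), 0.12)
  expect_gt(s1, s0)
})

test_that("noiseless patterns repeat exactly and carry no baseline noise confound", {
  cfg <- small_config()
  gt <- make_ground_truth(cfg)
  tr <- generate_trial_sequence(cfg, seed = 2)
  rg <- region_spec("clean", n_voxels = 12, w_shared = 1, sigma_noise = 0)
  ps <- simulate_voxel_patterns(gt, 1, rg, tr)
  same_ex <- which(tr$category == tr$category[1] &
                     tr$exemplar == tr$exemplar[1])
  for (t in same_ex[-1])
    expect_equal(ps$patterns[t, ], ps$patterns[same_ex[1], ])
})

test_that("identical seeds reproduce every simulated artifact", {
  st1 <- simulate_study(small_config(seed = 17), regions = small_regions())
  st2 <- simulate_study(small_config(seed = 17), regions = small_regions())
  expect_identical(st1$arrangements, st2$arrangements)
  expect_identical(st1$trials, st2$trials)
  expect_identical(st1$behaviour, st2$behaviour)
  expect_identical(st1$patterns$signal[[2]]$patterns,
                   st2$patterns$signal[[2]]$patterns)
})

test_that("noiseless end-to-end recovery reaches the ground-truth ranks", {
  cfg <- small_config()
  gt <- make_ground_truth(cfg, sigma_place = 0)
  tr <- generate_trial_sequence(cfg, seed = 3)
  # the shared baseline map keeps 1 - Pearson r locally monotone in the
  # latent distances, so ranks are recovered almost perfectly
  rg <- region_spec("clean", n_voxels = 24, w_observer = 1, sigma_noise = 0)
  for (o in 1:2) {
    td <- true_distances(gt, o)
    beh <- build_behaviour_rdm(simulate_arrangements(gt, o, sigma_place = 0))
    expect_equal(stats::cor(beh$percentile, td$distance,
                            method = "spearman"), 1)
    ps <- simulate_voxel_patterns(gt, o, rg, tr)
    brain <- build_brain_rdm(exemplar_mean_patterns(ps))
    expect_gt(stats::cor(brain$raw, td$distance, method = "spearman"), 0.95)
  }
})
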