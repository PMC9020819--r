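fake_rdm <- function(p, observer = 1) {
  pairs <- pair_table()
  n_cat <- length(p) / 6L
  data.frame(observer = observer, category = rep(seq_len(n_cat), each = 6L),
             i = rep(pairs$i, n_cat), j = rep(pairs$j, n_cat),
             raw = p, percentile = p)
}

test_that("RDM correlation handles identity, shuffling and level subsets", {
  set.seed(1)
  p <- to_percentiles(runif(60))
  a <- fake_rdm(p)
  expect_equal(brain_behaviour_correlation(a, a)$r, 1)
  null_r <- vapply(1:200, function(i)
    brain_behaviour_correlation(a, fake_rdm(sample(p)))$r, 0)
  expect_lt(abs(mean(null_r)), 0.05)
  part <- stratify_levels(a)
  res <- brain_behaviour_correlation(a, a, subset = "high", partition = part)
  expect_equal(res$r, 1)
  expect_equal(res$n_entries, sum(part$level == "high"))
  expect_error(brain_behaviour_correlation(a[1:2, ], a[1:2, ]), "aligned")
})

test_that("group inference follows the t-test at the extremes", {
  expect_equal(group_inference(rep(0, 10))$t, 0)
  expect_equal(group_inference(rep(0, 10))$p_raw, 0.5)
  deg <- group_inference(rep(0.5, 10))
  expect_true(deg$p_raw <= .Machine$double.xmin)
  set.seed(2)
  r <- runif(12, 0.2, 0.6)
  gi <- group_inference(r, n_tests = 4)
  tt <- t.test(atanh(r), alternative = "greater")
  expect_equal(gi$t, unname(tt$statistic))
  expect_equal(gi$p_bonferroni, min(1, tt$p.value * 4))
})

test_that("region comparison is antisymmetric and null on identical copies", {
  set.seed(3)
  ra <- runif(10, 0.1, 0.5); rb <- runif(10, 0.1, 0.5)
  expect_equal(compare_regions(ra, ra)$t, 0)
  ab <- compare_regions(ra, rb); ba <- compare_regions(rb, ra)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_error(compare_regions(ra, rb[1:5]), "same observers")
})

test_that("i-index vanishes when all behaviour RDMs are identical", {
  set.seed(4)
  p <- to_percentiles(runif(60))
  behaviours <- lapply(1:5, function(o) fake_rdm(p, o))
  brains <- lapply(1:5, function(o) fake_rdm(to_percentiles(runif(60)), o))
  res <- i_index(brains, behaviours)
  expect_equal(res$i, rep(0, 5), tolerance = 1e-12)
})

test_that("i-index is antisymmetric under swapping own and other at n = 2", {
  set.seed(5)
  behaviours <- lapply(1:2, function(o) fake_rdm(to_percentiles(runif(60)), o))
  brains <- lapply(1:2, function(o) fake_rdm(to_percentiles(runif(60)), o))
  res <- i_index(brains, behaviours)
  swapped <- i_index(brains, behaviours[c(2, 1)])
  expect_equal(res$i, -swapped$i)
})

test_that("i-index results are invariant to observer ordering", {
  set.seed(6)
  behaviours <- lapply(1:5, function(o) fake_rdm(to_percentiles(runif(60)), o))
  brains <- lapply(1:5, function(o) fake_rdm(to_percentiles(runif(60)), o))
  res <- i_index(brains, behaviours)
  ord <- c(3, 1, 5, 2, 4)
  res2 <- i_index(brains[ord], behaviours[ord])
  expect_equal(res2$i, res$i[ord])
  expect_equal(res2$mean_i, res$mean_i)
})

test_that("permutation p-values are valid, reproducible and centred", {
  set.seed(7)
  behaviours <- lapply(1:8, function(o) fake_rdm(to_percentiles(runif(60)), o))
  brains <- lapply(1:8, function(o) fake_rdm(to_percentiles(runif(60)), o))
  M <- cross_correlation_matrix(brains, behaviours)
  r1 <- permutation_null_i_index(M, n_perm = 500, seed = 9)
  r2 <- permutation_null_i_index(M, n_perm = 500, seed = 9)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gt(r1$p_perm, 0)
  expect_lte(r1$p_perm, 1)
  # a null i-index should sit in the body of its own permutation distribution
  expect_gt(r1$p_perm, 0.01)
  expect_error(permutation_null_i_index(M, n_perm = 50), "100")
})

test_that("average RDM equals any single observer when all agree", {
  set.seed(8)
  p <- to_percentiles(runif(60))
  rdms <- do.call(rbind, lapply(1:4, function(o) fake_rdm(p, o)))
  avg <- average_rdm(rdms)
  one <- fake_rdm(p)
  ord_a <- order(avg$category, avg$i, avg$j)
  ord_o <- order(one$category, one$i, one$j)
  expect_equal(avg$percentile[ord_a], one$percentile[ord_o])
  expect_equal(model_rdm_correlation(avg, one)$r, 1)
})

test_that("model RDM correlates with feature-coupled regions only", {
  cfg <- study_config(n_observers = 8, n_runs = 4, seed = 31)
  # alpha = 0: model features orthogonal to perceived structure, so only
  # regions that read the features out should correlate with the model RDM
  st <- simulate_study(cfg, regions = list(
    feat = region_spec("feat", n_voxels = 40, w_intermediate = 1,
                       sigma_noise = 1),
    percept = region_spec("percept", n_voxels = 40, w_observer = 1,
                          sigma_noise = 1)), alpha_intermediate = 0)
  mod <- intermediate_feature_rdm(st$ground_truth)
  r <- sapply(c("feat", "percept"), function(rg)
    mean(vapply(1:8, function(o) {
      brain <- build_brain_rdm(
        exemplar_mean_patterns(st$patterns[[rg]][[o]]), o, rg)
      model_rdm_correlation(mod, brain)$r
    }, 0)))
  # both regions share the coarse twin/cross geometry with the model, but
  # only the feature-coupled region tracks the model's full structure
  expect_gt(r["feat"], 0.6)
  expect_gt(r["feat"], r["percept"] + 0.1)
})
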