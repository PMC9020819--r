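test_that("arena distances follow analytic geometry", {
  sq <- data.frame(observer = 1, category = 1, exemplar = 1:4,
                   x = c(0, 0.5, 0, 0.5), y = c(0, 0, 0.5, 0.5))
  d <- distances_from_arrangement(sq)
  expect_equal(nrow(d), 6L)
  expect_equal(sort(d$distance),
               sort(c(0.5, 0.5, 0.5, 0.5, sqrt(0.5), sqrt(0.5))))
  coincident <- data.frame(observer = 1, category = 1, exemplar = 1:4,
                           x = 0.1, y = -0.2)
  expect_equal(distances_from_arrangement(coincident)$distance, rep(0, 6))
  dup <- sq; dup$exemplar <- c(1, 1, 2, 3)
  expect_error(distances_from_arrangement(dup), "duplicate")
})

test_that("behaviour RDMs have the 60-entry within-category support", {
  st <- small_behaviour_cohort()
  rdm <- build_behaviour_rdm(
    st$arrangements[st$arrangements$observer == 1, ])
  expect_equal(nrow(rdm), 60L)
  expect_equal(as.vector(table(rdm$category)), rep(6L, 10L))
  expect_true(all(rdm$i < rdm$j))
  expect_equal(sort(rdm$percentile)[c(1, 60)], c(0, 1))

  one_cat <- st$arrangements[st$arrangements$observer == 1 &
                               st$arrangements$category == 3, ]
  r1 <- build_behaviour_rdm(one_cat)
  expect_equal(nrow(r1), 6L)
  expect_equal(range(r1$percentile), c(0, 1))

  expect_error(build_behaviour_rdm(
    st$arrangements[st$arrangements$observer == 1 &
                      st$arrangements$category < 10, ],
    n_categories = 10), "category: 10")
})

test_that("identical arrangements give identical RDMs", {
  st <- small_behaviour_cohort()
  a <- st$arrangements[st$arrangements$observer == 2, ]
  b <- a; b$observer <- 9
  ra <- build_behaviour_rdm(a); rb <- build_behaviour_rdm(b)
  expect_equal(ra$percentile, rb$percentile)
  expect_equal(ra$raw, rb$raw)
})

test_that("level stratification applies the 2-2-2 split and the gap rule", {
  mk <- function(p) data.frame(observer = 1, category = 1,
                               i = pair_table()$i, j = pair_table()$j,
                               raw = p, percentile = p)
  s1 <- stratify_levels(mk(c(0.1, 0.1, 0.5, 0.5, 0.9, 0.9)), min_gap = 0.1)
  expect_equal(s1$level, c("high", "high", "medium", "medium", "low", "low"))
  # boundary gap 0.05 between 0.16 and 0.21 excludes both straddling entries
  s2 <- stratify_levels(mk(c(0.10, 0.16, 0.21, 0.5, 0.8, 0.9)),
                        min_gap = 0.1)
  expect_equal(s2$level,
               c("high", "excluded", "excluded", "medium", "low", "low"))
})

test_that("level stratification matches the sort-and-partition oracle", {
  set.seed(13)
  pairs <- pair_table()
  for (rep in 1:1000) {
    p <- round(stats::runif(6), 2)  # rounding creates frequent near-ties
    rdm <- data.frame(observer = 1, category = 1, i = pairs$i, j = pairs$j,
                      raw = p, percentile = p)
    expect_identical(stratify_levels(rdm, min_gap = 0.1)$level,
                     brute_stratify(p, min_gap = 0.1))
  }
})

test_that("level assignment is invariant to exemplar relabelling", {
  st <- small_behaviour_cohort()
  rdm <- build_behaviour_rdm(st$arrangements[st$arrangements$observer == 1, ])
  part <- stratify_levels(rdm)
  relab <- c(3L, 1L, 4L, 2L)  # permute exemplar ids
  rdm2 <- rdm
  rdm2$i <- pmin(relab[rdm$i], relab[rdm$j])
  rdm2$j <- pmax(relab[rdm$i], relab[rdm$j])
  part2 <- stratify_levels(rdm2)
  key1 <- paste(part$category, pmin(relab[part$i], relab[part$j]),
                pmax(relab[part$i], relab[part$j]))
  expect_equal(part2$level[match(key1, paste(part2$category, part2$i,
                                             part2$j))],
               part$level)
})

test_that("level means are ordered high < medium < low in dissimilarity", {
  st <- small_behaviour_cohort()
  for (o in seq_len(st$config$n_observers)) {
    rdm <- build_behaviour_rdm(st$arrangements[st$arrangements$observer == o, ])
    part <- stratify_levels(rdm)
    m <- tapply(part$percentile, part$level, mean)
    expect_true(m["high"] < m["medium"] && m["medium"] < m["low"])
  }
})

test_that("leave-one-out intersubject correlation behaves at the extremes", {
  st <- small_behaviour_cohort()
  rdms <- behaviour_rdms_of(st)
  identical_cohort <- do.call(rbind, lapply(1:4, function(o) {
    r <- rdms[[1]]; r$observer <- o; r
  }))
  res <- intersubject_correlation(identical_cohort)
  expect_equal(res$per_observer$r, rep(1, 4))

  set.seed(3)
  noisy <- rdms
  noisy[[1]]$percentile <- stats::runif(60)
  res2 <- intersubject_correlation(do.call(rbind, noisy))
  expect_lt(abs(res2$per_observer$r[1]), 0.35)
  expect_gt(min(res2$per_observer$r[-1]), res2$per_observer$r[1])
  expect_error(intersubject_correlation(rdms[[1]]), "3 observers")
})
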