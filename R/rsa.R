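#' Correlate a brain RDM with a behaviour RDM
#'
#' Pearson correlation over aligned within-category entries; for a level
#' subset the entries are restricted to the BEHAVIOUR owner's partition for
#' that level (excluded pairs are dropped from both sides).
#'
#' @param brain brain RDM data.frame.
#' @param behaviour behaviour RDM data.frame.
#' @param subset `"whole"`, `"low"`, `"medium"` or `"high"`.
#' @param partition the behaviour owner's level partition (required for
#'   level subsets).
#' @return list of class `rdm_correlation`: `r`, `z` (Fisher), `n_entries`,
#'   `subset`.
#' @export
brain_behaviour_correlation <- function(brain, behaviour, subset = "whole",
                                        partition = NULL) {
  stopifnot(subset %in% c("whole", "low", "medium", "high"))
  if (subset != "whole") {
    if (is.null(partition))
      stop("level subsets need the behaviour owner's partition")
    keys <- rdm_key(partition[partition$level == subset, ])
    brain <- brain[rdm_key(brain) %in% keys, ]
    behaviour <- behaviour[rdm_key(behaviour) %in% keys, ]
  }
  al <- align_rdms(brain, behaviour)
  r <- stats::cor(al$a, al$b)
  structure(list(r = r, z = fisher_z(r), n_entries = length(al$a),
                 subset = subset),
            class = "rdm_correlation")
}

#' Generic model-RDM correlation
#'
#' Correlates any model RDM (e.g. intermediate-feature or C2-based) with a
#' target RDM (a brain RDM, or an average behaviour RDM) over aligned
#' entries, optionally restricted to a similarity level of a partition.
#' Identical machinery to [brain_behaviour_correlation()] with the model in
#' the role of the behaviour side.
#'
#' @inheritParams brain_behaviour_correlation
#' @param model_rdm,target_rdm RDM data.frames with `category`, `i`, `j`,
#'   `percentile`.
#' @export
model_rdm_correlation <- function(model_rdm, target_rdm, subset = "whole",
                                  partition = NULL) {
  brain_behaviour_correlation(target_rdm, model_rdm, subset = subset,
                              partition = partition)
}

#' Element-wise average behaviour RDM
#'
#' The cohort-average perceived-similarity RDM: the mean of all observers'
#' percentile entries per pair, re-expressed as percentiles.
#'
#' @param rdms stacked behaviour RDMs over observers.
#' @return RDM data.frame (`category`, `i`, `j`, `raw`, `percentile`).
#' @export
average_rdm <- function(rdms) {
  wide <- rdm_matrix(rdms)
  parts <- strsplit(rownames(wide), "_")
  out <- data.frame(category = as.integer(vapply(parts, `[`, "", 1L)),
                    i = as.integer(vapply(parts, `[`, "", 2L)),
                    j = as.integer(vapply(parts, `[`, "", 3L)),
                    raw = rowMeans(wide))
  out$percentile <- to_percentiles(out$raw)
  rdm_sort(out)
}

#' Group inference on per-observer correlations
#'
#' One-sample t-test of the Fisher-z transformed correlations against 0,
#' one-sided (r > 0) by default, Bonferroni-corrected for the size of the
#' test family (regions, or regions x levels).
#'
#' @param r numeric vector of per-observer correlations.
#' @param n_tests size of the Bonferroni family.
#' @param alternative passed to [stats::t.test()].
#' @return data.frame with `mean_r`, `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `n_tests`.
#' @export
group_inference <- function(r, n_tests = 1L, alternative = "greater") {
  z <- fisher_z(r)
  if (stats::sd(z) == 0) {
    # degenerate: identical correlations across observers
    p <- if (mean(z) > 0 && alternative != "less") .Machine$double.xmin
         else if (mean(z) == 0) if (alternative == "two.sided") 1 else 0.5
         else 1
    tt <- list(statistic = if (mean(z) == 0) 0 else sign(mean(z)) * Inf,
               parameter = length(r) - 1L, p.value = p)
  } else {
    tt <- stats::t.test(z, alternative = alternative)
  }
  data.frame(mean_r = mean(r), t = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             p_bonferroni = min(1, tt$p.value * n_tests),
             n_tests = n_tests)
}

#' Paired comparison of two regions' brain-behaviour correlations
#'
#' Paired t-test on the Fisher-z differences between two regions over the
#' same observers (two-sided), Bonferroni-corrected for the number of
#' requested contrasts.
#'
#' @param r_a,r_b per-observer correlation vectors for the two regions, in
#'   the same observer order.
#' @param n_contrasts Bonferroni family size.
#' @return data.frame with `mean_diff_z`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`.
#' @export
compare_regions <- function(r_a, r_b, n_contrasts = 1L) {
  if (length(r_a) != length(r_b))
    stop("region comparison needs the same observers in both regions")
  d <- fisher_z(r_a) - fisher_z(r_b)
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1L,
               p.value = if (mean(d) == 0) 1 else .Machine$double.xmin)
  } else {
    tt <- stats::t.test(d)
  }
  data.frame(mean_diff_z = mean(d), t = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             p_bonferroni = min(1, tt$p.value * n_contrasts))
}

#' Within/between-observer brain-behaviour correlation matrix
#'
#' `M[o, p]` is the correlation between observer `o`'s brain RDM and
#' observer `p`'s behaviour RDM; for level subsets each column `p` is
#' restricted by the behaviour OWNER `p`'s partition. The diagonal holds
#' the within-subject correlations, the off-diagonal the between-subject
#' ones; all i-index statistics derive from this matrix.
#'
#' @param brains list of brain RDMs, one per observer (same order as
#'   `behaviours`).
#' @param behaviours list of behaviour RDMs, one per observer.
#' @param subset `"whole"` or a level name.
#' @param partitions list of level partitions, one per observer (required
#'   for level subsets).
#' @return n x n numeric matrix.
#' @export
cross_correlation_matrix <- function(brains, behaviours, subset = "whole",
                                     partitions = NULL) {
  n <- length(brains)
  if (length(behaviours) != n)
    stop("brains and behaviours must cover the same observers")
  M <- matrix(NA_real_, n, n)
  for (p in seq_len(n)) {
    part <- if (subset == "whole") NULL else partitions[[p]]
    for (o in seq_len(n))
      M[o, p] <- brain_behaviour_correlation(brains[[o]], behaviours[[p]],
                                             subset = subset,
                                             partition = part)$r
  }
  M
}

#' Observer-specificity i-index
#'
#' For each observer, the within-subject brain-behaviour correlation minus
#' the mean of the between-subject correlations of their brain RDM with
#' every OTHER observer's behaviour RDM. Positive values mean the region's
#' patterns track the observer's own perceived structure better than other
#' observers'.
#'
#' @param M cross-correlation matrix from [cross_correlation_matrix()], or
#'   a list of brain RDMs (then `behaviours`/`subset`/`partitions` are used
#'   to build it).
#' @inheritParams cross_correlation_matrix
#' @return list of class `i_index`: per-observer `within_r`, `between_r`,
#'   `i`, plus `mean_i` and `n_observers`.
#' @export
i_index <- function(M, behaviours = NULL, subset = "whole",
                    partitions = NULL) {
  if (!is.matrix(M))
    M <- cross_correlation_matrix(M, behaviours, subset, partitions)
  n <- nrow(M)
  if (n < 2L) stop("i-index needs at least 2 observers")
  within <- diag(M)
  between <- (rowSums(M) - within) / (n - 1L)
  structure(list(within_r = within, between_r = between,
                 i = within - between, mean_i = mean(within - between),
                 n_observers = n, subset = subset, M = M),
            class = "i_index")
}

#' @export
print.i_index <- function(x, ...) {
  cat(sprintf("i-index (%s): mean %.4f over %d observers\n",
              x$subset, x$mean_i, x$n_observers))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.4g (%d permutations), SEM = %.4f\n",
                x$p_perm, x$n_perm, x$sem_randomization))
  invisible(x)
}

#' Subject-label permutation test for the i-index
#'
#' Builds a null distribution for the group-mean i-index by randomly
#' permuting the observer labels of the behaviour RDMs (permutations may
#' map labels to themselves) and recomputing the group mean on each draw.
#' The p-value uses the add-one convention, `(1 + #[null >= observed]) /
#' (1 + n_perm)`, so it is never exactly 0; the SEM is the standard
#' deviation of the null distribution.
#'
#' Only the cross-correlation matrix is needed: a label permutation `pi`
#' replaces observer `o`'s within-correlation by `M[o, pi(o)]` while the
#' observer's mean correlation with all behaviour RDMs is unchanged, so
#' each draw is O(n).
#'
#' @inheritParams i_index
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return an `i_index` object with `p_perm`, `sem_randomization`,
#'   `n_perm`, `null_mean_i` and `seed` added.
#' @export
permutation_null_i_index <- function(M, behaviours = NULL, subset = "whole",
                                     partitions = NULL, n_perm = 10000L,
                                     seed = 1L) {
  if (n_perm < 100L) stop("use at least 100 permutations")
  res <- i_index(M, behaviours, subset, partitions)
  M <- res$M
  n <- res$n_observers
  row_sum <- rowSums(M)
  set.seed(derive_seed(seed, "i-index-permutation"))
  null_i <- vapply(seq_len(n_perm), function(b) {
    pi_b <- sample.int(n)
    w <- M[cbind(seq_len(n), pi_b)]
    mean(w - (row_sum - w) / (n - 1L))
  }, 0)
  res$p_perm <- (1 + sum(null_i >= res$mean_i)) / (1 + n_perm)
  res$sem_randomization <- stats::sd(null_i)
  res$n_perm <- as.integer(n_perm)
  res$null_mean_i <- mean(null_i)
  res$seed <- seed
  res
}
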