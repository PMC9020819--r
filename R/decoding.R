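#' Run-wise exemplar mean patterns
#'
#' One mean voxel vector per (run, exemplar) over no-response trials; these
#' are the classification samples, with runs defining the cross-validation
#' folds. Errors if any exemplar is missing from any run.
#'
#' @param ps a `pattern_set`.
#' @return list with `patterns` (cells x voxels matrix) and `index`
#'   (data.frame `run`, `category`, `exemplar`).
#' @export
runwise_patterns <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  idx <- ps$index
  keep <- idx$trial_type == "no_response"
  key <- paste(idx$run, idx$category, idx$exemplar)[keep]
  runs <- sort(unique(idx$run))
  cells <- expand.grid(exemplar = sort(unique(idx$exemplar)),
                       category = sort(unique(idx$category)),
                       run = runs)[, c("run", "category", "exemplar")]
  cell_keys <- paste(cells$run, cells$category, cells$exemplar)
  missing <- cell_keys[!cell_keys %in% key]
  if (length(missing))
    stop("no no-response trials for (run, category, exemplar) cell(s): ",
         paste(utils::head(missing, 5L), collapse = "; "))
  g <- factor(key, levels = cell_keys)
  means <- rowsum(ps$patterns[keep, , drop = FALSE], g) / as.vector(table(g))
  rownames(cells) <- NULL
  list(patterns = means, index = cells)
}

#' Leave-one-run-out pairwise decoding accuracy
#'
#' Linear maximum-margin classification of one exemplar pair: for each
#' fold, a linear support-vector classifier (cost fixed at 1) is trained on
#' the two exemplars' run-wise patterns from all other runs — features
#' standardized with training-fold statistics only — and tested on the
#' held-out run's two patterns. Accuracy is averaged over folds; chance is
#' 0.5. Degenerate training data (identical classes) yields 0.5 with a
#' warning.
#'
#' @param rw run-wise patterns from [runwise_patterns()].
#' @param category category of the pair.
#' @param i,j the two exemplars.
#' @param cost SVM regularization constant.
#' @return cross-validated accuracy in `[0, 1]`.
#' @export
pairwise_accuracy <- function(rw, category, i, j, cost = 1) {
  idx <- rw$index
  runs <- sort(unique(idx$run))
  if (length(runs) < 2L)
    stop("leave-one-run-out decoding needs at least 2 runs")
  sel <- idx$category == category & idx$exemplar %in% c(i, j)
  X <- rw$patterns[sel, , drop = FALSE]
  y <- factor(idx$exemplar[sel], levels = c(i, j))
  run <- idx$run[sel]
  acc <- vapply(runs, function(r) {
    tr <- run != r
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    fit <- tryCatch(
      e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost, scale = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    mean(stats::predict(fit, Xte) == y[!tr])
  }, 0)
  if (anyNA(acc)) {
    warning("degenerate training data for pair (", category, ": ", i, ",",
            j, "); accuracy reported as chance")
    acc[is.na(acc)] <- 0.5
  }
  mean(acc)
}

#' Level-wise decoding of one observer and region
#'
#' Decodes every exemplar pair retained by a level partition and averages
#' the pairwise accuracies within each similarity level.
#'
#' @param ps a `pattern_set`.
#' @param partition level partition for the observer whose perceived
#'   structure defines the levels (their own, in the main analysis).
#' @param levels which levels to decode.
#' @param cost SVM regularization constant.
#' @return list with `pairs` (data.frame `category`, `i`, `j`, `level`,
#'   `accuracy`) and `by_level` (data.frame `level`, `n_pairs`,
#'   `accuracy`).
#' @export
level_decoding <- function(ps, partition, levels = c("low", "medium", "high"),
                           cost = 1) {
  rw <- runwise_patterns(ps)
  part <- partition[partition$level %in% levels, ]
  if (!nrow(part)) stop("partition retains no pairs at the requested levels")
  part$accuracy <- vapply(seq_len(nrow(part)), function(ri)
    pairwise_accuracy(rw, part$category[ri], part$i[ri], part$j[ri],
                      cost = cost), 0)
  by_level <- do.call(rbind, lapply(levels, function(L) {
    s <- part[part$level == L, ]
    if (!nrow(s)) {
      warning("no retained pairs at level '", L, "'")
      return(NULL)
    }
    data.frame(level = L, n_pairs = nrow(s), accuracy = mean(s$accuracy))
  }))
  list(pairs = part[, c("category", "i", "j", "level", "accuracy")],
       by_level = by_level)
}

#' Group test of decoding accuracy against chance
#'
#' One-tailed one-sample t-test of per-observer level-mean accuracies
#' against 0.5, Bonferroni-corrected over the regions x levels family.
#'
#' @param accuracies per-observer mean accuracies for one region and level.
#' @param n_tests Bonferroni family size (regions x levels).
#' @return data.frame with `mean_accuracy`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`.
#' @export
decoding_group_test <- function(accuracies, n_tests = 1L) {
  d <- accuracies - 0.5
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1L,
               p.value = if (mean(d) > 0) .Machine$double.xmin
                         else if (mean(d) == 0) 0.5 else 1)
  } else {
    tt <- stats::t.test(d, alternative = "greater")
  }
  data.frame(mean_accuracy = mean(accuracies), t = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             p_bonferroni = min(1, tt$p.value * n_tests))
}
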