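#' Exemplar-mean voxel patterns
#'
#' Averages each exemplar's no-response trials (catch trials are excluded
#' from all pattern analyses) into one voxel vector, optionally restricted
#' to a subset of runs; under the default design each mean aggregates 24
#' trials.
#'
#' @param ps a `pattern_set`.
#' @param run_subset runs to include; `NULL` for all.
#' @return list with `means` (exemplars x voxels matrix), `index`
#'   (data.frame `category`, `exemplar`) and `n_trials` per exemplar.
#' @export
exemplar_mean_patterns <- function(ps, run_subset = NULL) {
  stopifnot(inherits(ps, "pattern_set"))
  idx <- ps$index
  keep <- idx$trial_type == "no_response"
  if (!is.null(run_subset)) keep <- keep & idx$run %in% run_subset
  if (!any(keep)) stop("no qualifying no-response trials in run subset")
  key <- paste(idx$category, idx$exemplar)[keep]
  ex_tab <- unique(idx[, c("category", "exemplar")])
  ex_tab <- ex_tab[order(ex_tab$category, ex_tab$exemplar), ]
  ex_keys <- paste(ex_tab$category, ex_tab$exemplar)
  missing <- ex_keys[!ex_keys %in% key]
  if (length(missing))
    stop("no no-response trials for exemplar(s): ",
         paste(missing, collapse = "; "))
  P <- ps$patterns[keep, , drop = FALSE]
  g <- factor(key, levels = ex_keys)
  means <- rowsum(P, g) / as.vector(table(g))
  rownames(ex_tab) <- NULL
  list(means = means, index = ex_tab, n_trials = as.vector(table(g)))
}

#' Build a brain-based RDM from exemplar means
#'
#' Pairwise pattern dissimilarity is 1 - Pearson's r between the two
#' exemplars' mean voxel vectors, computed for all within-category pairs
#' and percentile-converted with the same pooling convention as behaviour
#' RDMs (over the 60 within-category entries under the defaults).
#'
#' @param em output of [exemplar_mean_patterns()].
#' @param observer,region labels carried into the output.
#' @return RDM data.frame with columns `observer`, `region`, `category`,
#'   `i`, `j`, `raw` (1 - r) and `percentile`.
#' @export
build_brain_rdm <- function(em, observer = NA, region = NA) {
  means <- em$means
  if (ncol(means) < 2L) stop("brain RDM needs at least 2 voxels")
  v <- apply(means, 1L, stats::sd)
  if (any(v == 0))
    stop("zero-variance pattern for exemplar(s): ",
         paste(which(v == 0), collapse = ", "),
         "; 1 - Pearson r is undefined")
  idx <- em$index
  out <- do.call(rbind, lapply(unique(idx$category), function(k) {
    rows <- which(idx$category == k)
    pairs <- pair_table(length(rows))
    d <- vapply(seq_len(nrow(pairs)), function(pi) {
      1 - stats::cor(means[rows[pairs$i[pi]], ], means[rows[pairs$j[pi]], ])
    }, 0)
    data.frame(observer = observer, region = region, category = k,
               i = idx$exemplar[rows][pairs$i], j = idx$exemplar[rows][pairs$j],
               raw = d)
  }))
  out$percentile <- to_percentiles(out$raw)
  rdm_sort(out)
}

#' Split-half stability of a region's RDM
#'
#' Computes the brain RDM separately on two halves of the runs (odd vs even
#' by default) and correlates the two halves' percentile entries, optionally
#' restricted to one similarity level of a supplied partition. Values near 1
#' indicate that the pattern geometry is reliable across acquisition halves.
#'
#' @param ps a `pattern_set` with at least 2 runs.
#' @param subset `"whole"` or a level name.
#' @param partition level partition data.frame for this observer (needed for
#'   level subsets).
#' @param halves optional list of two run vectors; defaults to odd/even runs.
#' @return Pearson correlation between the two half RDMs.
#' @export
split_half_stability <- function(ps, subset = "whole", partition = NULL,
                                 halves = NULL) {
  runs <- sort(unique(ps$index$run))
  if (length(runs) < 2L) stop("split-half stability needs at least 2 runs")
  if (is.null(halves))
    halves <- list(runs[seq_along(runs) %% 2L == 1L],
                   runs[seq_along(runs) %% 2L == 0L])
  rdm1 <- build_brain_rdm(exemplar_mean_patterns(ps, halves[[1L]]))
  rdm2 <- build_brain_rdm(exemplar_mean_patterns(ps, halves[[2L]]))
  if (subset != "whole") {
    if (is.null(partition)) stop("level subsets need a partition")
    keys <- rdm_key(partition[partition$level == subset, ])
    rdm1 <- rdm1[rdm_key(rdm1) %in% keys, ]
    rdm2 <- rdm2[rdm_key(rdm2) %in% keys, ]
  }
  al <- align_rdms(rdm1, rdm2)
  stats::cor(al$a, al$b)
}
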