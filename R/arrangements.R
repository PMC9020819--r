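#' Pairwise distances from one arena arrangement
#'
#' The 4 exemplars of a category arranged in the arena yield the 6 pairwise
#' Euclidean distances that populate the behaviour RDM. Pairs are returned
#' in canonical lexicographic order (i < j).
#'
#' @param arrangement data.frame for ONE observer x category with columns
#'   `exemplar`, `x`, `y`.
#' @return data.frame with columns `i`, `j`, `distance`.
#' @export
distances_from_arrangement <- function(arrangement) {
  ex <- arrangement$exemplar
  if (anyDuplicated(ex)) stop("duplicate exemplar ids in arrangement")
  ord <- order(ex)
  xy <- as.matrix(arrangement[ord, c("x", "y")])
  if (any(sqrt(rowSums(xy^2)) > 1 + 1e-6))
    stop("arrangement coordinates fall outside the unit-radius arena")
  pairs <- pair_table(nrow(xy))
  d <- sqrt(rowSums((xy[pairs$i, , drop = FALSE] -
                       xy[pairs$j, , drop = FALSE])^2))
  data.frame(i = ex[ord][pairs$i], j = ex[ord][pairs$j], distance = d)
}

#' Build one observer's behaviour-based RDM
#'
#' Collects the 6 within-category pairwise distances from each category's
#' arrangement and converts them to dissimilarity percentiles pooled over
#' all of the observer's within-category pairs (60 under the default
#' design), producing the observer-specific perceived-similarity RDM.
#'
#' @param arrangements data.frame of one observer's arrangements (columns
#'   `observer`, `category`, `exemplar`, `x`, `y`), one arrangement per
#'   category.
#' @param n_categories expected number of categories (1..n), or `NULL` to
#'   accept whatever categories are present.
#' @return RDM data.frame with columns `observer`, `category`, `i`, `j`,
#'   `raw` (arena units) and `percentile`.
#' @export
build_behaviour_rdm <- function(arrangements, n_categories = NULL) {
  obs <- unique(arrangements$observer)
  if (length(obs) != 1L)
    stop("build_behaviour_rdm expects a single observer's arrangements")
  if (!is.null(n_categories)) {
    missing_cat <- setdiff(seq_len(n_categories),
                           unique(arrangements$category))
    if (length(missing_cat))
      stop("missing arrangement for category: ",
           paste(missing_cat, collapse = ", "))
  }
  cats <- sort(unique(arrangements$category))
  out <- do.call(rbind, lapply(cats, function(k) {
    d <- distances_from_arrangement(arrangements[arrangements$category == k, ])
    data.frame(observer = obs, category = k, i = d$i, j = d$j, raw = d$distance)
  }))
  out$percentile <- to_percentiles(out$raw)
  rdm_sort(out)
}

#' Stratify an RDM into low / medium / high similarity levels
#'
#' Per category the 6 dissimilarity percentiles are rank-ordered and split
#' 2-2-2: the two smallest dissimilarities form the HIGH-similarity level,
#' the two middle the MEDIUM, and the two largest the LOW. To keep levels
#' non-overlapping, whenever the percentile gap across a level boundary
#' (high-medium or medium-low) is smaller than `min_gap`, BOTH entries
#' straddling that boundary are marked `excluded`. Ties in the ranking are
#' broken by canonical pair order.
#'
#' @param rdm RDM data.frame with `category`, `i`, `j`, `percentile`.
#' @param min_gap minimum percentile separation between successive levels.
#' @return the RDM with an added `level` column in
#'   `c("high", "medium", "low", "excluded")`.
#' @export
stratify_levels <- function(rdm, min_gap = 0.1) {
  rdm <- rdm_sort(rdm)
  rdm$level <- NA_character_
  for (k in unique(rdm$category)) {
    rows <- which(rdm$category == k)
    if (length(rows) != 6L)
      stop("stratify_levels expects 6 pairs per category (category ", k,
           " has ", length(rows), ")")
    p <- rdm$percentile[rows]
    ord <- order(p)                       # ties: canonical pair order (stable)
    lev <- character(6L)
    lev[ord] <- c("high", "high", "medium", "medium", "low", "low")
    ps <- p[ord]
    if (ps[3L] - ps[2L] < min_gap) lev[ord[c(2L, 3L)]] <- "excluded"
    if (ps[5L] - ps[4L] < min_gap) lev[ord[c(4L, 5L)]] <- "excluded"
    rdm$level[rows] <- lev
  }
  rdm
}

#' Leave-one-out intersubject agreement of RDMs
#'
#' For each observer, the Pearson correlation between their RDM entries and
#' the element-wise mean of all other observers' entries, optionally
#' restricted to one similarity level of the observer's own partition.
#' Group inference is a one-sample t-test of the Fisher-z correlations
#' against 0 (one-sided, r > 0).
#'
#' @param rdms stacked RDM data.frame over observers (columns `observer`,
#'   `category`, `i`, `j`, `percentile`).
#' @param subset `"whole"` or one of `"low"`, `"medium"`, `"high"`.
#' @param partitions stacked partition data.frame (output of
#'   [stratify_levels()] over observers) — required for level subsets.
#' @return list with `per_observer` (data.frame `observer`, `r`), `mean_r`,
#'   `min_r`, `max_r`, `t`, `df`, `p`.
#' @export
intersubject_correlation <- function(rdms, subset = "whole",
                                     partitions = NULL) {
  observers <- sort(unique(rdms$observer))
  if (length(observers) < 3L)
    stop("intersubject correlation needs at least 3 observers")
  wide <- rdm_matrix(rdms, observers)
  r <- vapply(seq_along(observers), function(oi) {
    own <- wide[, oi]
    others <- rowMeans(wide[, -oi, drop = FALSE])
    keep <- rep(TRUE, length(own))
    if (subset != "whole") {
      if (is.null(partitions))
        stop("level subsets need the observers' partitions")
      part <- partitions[partitions$observer == observers[oi], ]
      keep <- rownames(wide) %in% rdm_key(part[part$level == subset, ])
    }
    if (sum(keep) < 3L)
      stop("fewer than 3 common entries in subset '", subset, "'")
    stats::cor(own[keep], others[keep])
  }, 0)
  z <- fisher_z(r)
  tt <- if (stats::sd(z) == 0) {
    list(statistic = if (mean(z) == 0) 0 else sign(mean(z)) * Inf,
         parameter = length(z) - 1L,
         p.value = if (mean(z) > 0) .Machine$double.xmin
                   else if (mean(z) == 0) 0.5 else 1)
  } else {
    stats::t.test(z, alternative = "greater")
  }
  list(per_observer = data.frame(observer = observers, r = r),
       mean_r = mean(r), min_r = min(r), max_r = max(r),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# entries x observers matrix of percentiles, aligned on (category, i, j)
rdm_matrix <- function(rdms, observers = sort(unique(rdms$observer))) {
  ref <- rdm_sort(unique(rdms[, c("category", "i", "j")]))
  keys <- rdm_key(ref)
  m <- vapply(observers, function(o) {
    sub <- rdms[rdms$observer == o, ]
    v <- sub$percentile[match(keys, rdm_key(sub))]
    if (anyNA(v)) stop("observer ", o, " is missing RDM entries")
    v
  }, numeric(length(keys)))
  rownames(m) <- keys
  m
}
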