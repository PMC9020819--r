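#' Convert dissimilarities to dissimilarity percentiles
#'
#' Rank-based normalization of raw dissimilarities to the unit interval,
#' making RDMs comparable across observers and across modalities (arena
#' distances, 1 - Pearson r, model feature distances). The percentile of a
#' value is `(average rank - 1) / (n - 1)`, with ties receiving averaged
#' ranks, so the smallest value maps to 0 and the largest to 1.
#'
#' The conversion is invariant to any strictly monotone transform of the
#' input. If all values are equal every percentile is 0.5 and a warning is
#' emitted.
#'
#' @param x numeric vector of dissimilarities, length >= 2.
#' @return numeric vector of percentiles in `[0, 1]`.
#' @export
to_percentiles <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("percentile conversion needs a numeric vector of length >= 2")
  if (anyNA(x)) stop("percentile conversion: NA dissimilarities")
  n <- length(x)
  if (max(x) == min(x)) {
    warning("all dissimilarities equal; percentiles set to 0.5")
    return(rep(0.5, n))
  }
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Canonical within-category pair table
#'
#' All unordered exemplar pairs (i < j) in lexicographic order; 4 exemplars
#' give the 6 pairwise distances each arena arrangement supports.
#'
#' @param n_exemplars exemplars per category.
#' @return data.frame with columns `i`, `j`.
#' @export
pair_table <- function(n_exemplars = 4L) {
  if (n_exemplars < 2L) stop("need at least 2 exemplars to form pairs")
  idx <- utils::combn(seq_len(n_exemplars), 2L)
  data.frame(i = idx[1L, ], j = idx[2L, ])
}

#' Fisher z transform
#' @param r correlations in \[-1, 1\].
#' @return atanh(r), clamped just inside +/-1 so perfect correlations stay finite.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# Deterministic child seed from a base seed and integer/character tags.
# Keeps results reproducible per (observer, region, stage) without a global
# RNG stream shared across unrelated stages. Always < 2^31.
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (tag in tags) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.numeric(tag)
    for (v in codes) h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# Key used to align RDM entries across observers / modalities.
rdm_key <- function(df) paste(df$category, df$i, df$j, sep = "_")

# Order an RDM data frame canonically (category, then pair).
rdm_sort <- function(df) df[order(df$category, df$i, df$j), , drop = FALSE]

# Align two RDM data frames on (category, i, j); returns list of matched
# percentile vectors. Errors if fewer than `min_n` shared entries.
align_rdms <- function(a, b, min_n = 3L) {
  ka <- rdm_key(a); kb <- rdm_key(b)
  common <- intersect(ka, kb)
  if (length(common) < min_n)
    stop(sprintf("only %d aligned RDM entries (need >= %d)", length(common), min_n))
  list(a = a$percentile[match(common, ka)],
       b = b$percentile[match(common, kb)],
       key = common)
}

# FNV-1a hash of a character scalar, hex string; used only for run manifests.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
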