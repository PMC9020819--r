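#' Generate a category-exemplar 1-back trial sequence
#'
#' Builds a randomized trial ordering satisfying the task's design
#' constraints, per run:
#' * every exemplar appears `reps_noresponse_per_run` times as a
#'   no-response trial and `reps_catch_per_run` times as a catch trial;
#' * a `same_exemplar_catch` repeats the immediately preceding exemplar, a
#'   `same_category_catch` repeats the preceding category with a different
#'   exemplar;
#' * consecutive no-response trials never share a category (so no-response
#'   trials are repetitions on neither level);
#' * a catch trial never opens a run.
#'
#' Under the defaults this yields 160 trials per run of which 120 (75%) are
#' no-response, and 24 no-response presentations per exemplar across 8 runs.
#' Generation is by constrained randomization with bounded restarts.
#'
#' @param config a [study_config()].
#' @param seed RNG seed for the ordering.
#' @param max_restarts restarts allowed per run before failing.
#' @return data.frame with columns `run`, `position`, `category`,
#'   `exemplar`, `trial_type`.
#' @export
generate_trial_sequence <- function(config, seed = config$seed,
                                    max_restarts = 200L) {
  stopifnot(inherits(config, "study_config"))
  set.seed(derive_seed(seed, "trials"))
  out <- lapply(seq_len(config$n_runs), function(r)
    cbind(run = r, one_run_sequence(config, max_restarts)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

one_run_sequence <- function(config, max_restarts) {
  n_cat <- config$n_categories
  n_ex <- config$n_exemplars_per_category
  r_nr <- config$reps_noresponse_per_run
  r_c <- config$reps_catch_per_run
  for (attempt in seq_len(max_restarts)) {
    nr <- order_noresponse(n_cat, n_ex, r_nr)
    if (is.null(nr)) next
    seqd <- attach_catches(nr, config)
    if (!is.null(seqd)) return(seqd)
  }
  stop(sprintf(paste0(
    "trial sequence generation failed after %d restarts: could not satisfy ",
    "the no-adjacent-category / catch-predecessor constraints ",
    "(%d categories x %d exemplars, %d no-response + %d catch reps)"),
    max_restarts, n_cat, n_ex, r_nr, r_c))
}

# Random ordering of no-response tokens with no two adjacent same-category
# tokens; returns NULL on a dead end.
order_noresponse <- function(n_cat, n_ex, r_nr) {
  remaining <- matrix(r_nr, n_cat, n_ex)  # counts per (category, exemplar)
  total <- n_cat * n_ex * r_nr
  cat_seq <- integer(total); ex_seq <- integer(total)
  prev <- 0L
  for (pos in seq_len(total)) {
    cat_counts <- rowSums(remaining)
    left <- total - pos + 1L
    # a category holding more than half the remaining tokens must be placed now
    forced <- which(cat_counts * 2L > left + 1L)
    if (length(forced) && forced[1L] == prev) return(NULL)
    cand <- if (length(forced)) forced else which(cat_counts > 0L)
    cand <- setdiff(cand, prev)
    if (!length(cand)) return(NULL)
    k <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = cat_counts[cand])
    e_av <- which(remaining[k, ] > 0L)
    e <- if (length(e_av) == 1L) e_av else
      sample(e_av, 1L, prob = remaining[k, e_av])
    remaining[k, e] <- remaining[k, e] - 1L
    cat_seq[pos] <- k; ex_seq[pos] <- e; prev <- k
  }
  data.frame(category = cat_seq, exemplar = ex_seq,
             trial_type = "no_response")
}

# Place each exemplar's catch presentations directly after a compatible
# no-response host; returns NULL if some catch finds no free host.
attach_catches <- function(nr, config) {
  n_cat <- config$n_categories
  n_ex <- config$n_exemplars_per_category
  r_c <- config$reps_catch_per_run
  catches <- expand.grid(category = seq_len(n_cat), exemplar = seq_len(n_ex),
                         rep = seq_len(r_c))
  is_ex <- stats::runif(nrow(catches)) < config$p_catch_exemplar
  if (n_ex == 1L) is_ex[] <- TRUE  # same-category repeats need a second exemplar
  catches$trial_type <- ifelse(is_ex, "same_exemplar_catch",
                               "same_category_catch")
  catches <- catches[sample(nrow(catches)), ]
  hosting <- logical(nrow(nr))
  host_of <- integer(nrow(catches))
  for (ci in seq_len(nrow(catches))) {
    k <- catches$category[ci]; e <- catches$exemplar[ci]
    ok <- !hosting & nr$category == k &
      (if (catches$trial_type[ci] == "same_exemplar_catch")
         nr$exemplar == e else nr$exemplar != e)
    cand <- which(ok)
    if (!length(cand)) return(NULL)
    h <- if (length(cand) == 1L) cand else sample(cand, 1L)
    hosting[h] <- TRUE
    host_of[ci] <- h
  }
  # weave catches in after their hosts
  after <- vector("list", nrow(nr))
  for (ci in seq_len(nrow(catches)))
    after[[host_of[ci]]] <- rbind(after[[host_of[ci]]],
                                  catches[ci, c("category", "exemplar",
                                                "trial_type")])
  rows <- vector("list", nrow(nr))
  for (t in seq_len(nrow(nr)))
    rows[[t]] <- rbind(nr[t, ], after[[t]])
  seqd <- do.call(rbind, rows)
  seqd$position <- seq_len(nrow(seqd))
  rownames(seqd) <- NULL
  seqd[, c("position", "category", "exemplar", "trial_type")]
}

#' Check a trial sequence against the design invariants
#'
#' @param trials data.frame from [generate_trial_sequence()].
#' @param config the [study_config()] it was generated from.
#' @return invisibly `TRUE`; stops with the violated invariant otherwise.
#' @export
validate_trial_sequence <- function(trials, config) {
  for (r in unique(trials$run)) {
    tr <- trials[trials$run == r, ]
    tr <- tr[order(tr$position), ]
    if (nrow(tr) != config$trials_per_run)
      stop("wrong trial count in run ", r)
    if (tr$trial_type[1L] != "no_response")
      stop("run ", r, " opens with a catch trial")
    prev_cat <- c(NA, tr$category[-nrow(tr)])
    prev_ex <- c(NA, tr$exemplar[-nrow(tr)])
    nr <- tr$trial_type == "no_response"
    if (any(tr$category[nr][-1L] == prev_cat[nr][-1L], na.rm = TRUE))
      stop("no-response trial repeats preceding category in run ", r)
    se <- tr$trial_type == "same_exemplar_catch"
    if (any(tr$category[se] != prev_cat[se] | tr$exemplar[se] != prev_ex[se]))
      stop("same-exemplar catch does not repeat its predecessor in run ", r)
    sc <- tr$trial_type == "same_category_catch"
    if (any(tr$category[sc] != prev_cat[sc] | tr$exemplar[sc] == prev_ex[sc]))
      stop("same-category catch violates its predecessor rule in run ", r)
    tab <- table(factor(tr$category, seq_len(config$n_categories)),
                 factor(tr$exemplar, seq_len(config$n_exemplars_per_category)),
                 tr$trial_type %in% c("same_exemplar_catch",
                                      "same_category_catch"))
    if (any(tab[, , 1L] != config$reps_noresponse_per_run) ||
        any(tab[, , 2L] != config$reps_catch_per_run))
      stop("per-exemplar presentation counts wrong in run ", r)
  }
  invisible(TRUE)
}
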