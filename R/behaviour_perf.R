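#' Score a category-exemplar 1-back log
#'
#' Classifies every trial of a behavioural log against its trial sequence.
#' Same-category catch trials are scored correct (same-category press),
#' same-exemplar confusion (the error of interest), or miss; same-exemplar
#' catches analogously; no-response trials are scored for false alarms.
#' Each catch trial is keyed by the (previous, current) exemplar pair so it
#' can be binned by perceived-similarity level.
#'
#' @param log behaviour data.frame (`response`, `rt`) aligned row-for-row
#'   with `trials`.
#' @param trials the trial sequence the log was recorded under.
#' @return data.frame of scored trials with columns `run`, `position`,
#'   `trial_type`, `category`, `i`, `j` (pair, `NA` on no-response trials),
#'   `outcome`, `rt`.
#' @export
score_oneback <- function(log, trials) {
  if (nrow(log) != nrow(trials))
    stop("log and trial sequence differ in length (",
         nrow(log), " vs ", nrow(trials), ")")
  n <- nrow(trials)
  prev_ex <- c(NA, trials$exemplar[-n])
  i <- pmin(trials$exemplar, prev_ex)
  j <- pmax(trials$exemplar, prev_ex)
  outcome <- character(n)
  for (t in seq_len(n)) {
    type <- trials$trial_type[t]; resp <- log$response[t]
    outcome[t] <- if (type == "no_response") {
      if (resp == "none") "correct_rejection" else "false_alarm"
    } else if (resp == "none") {
      "miss"
    } else if (type == "same_exemplar_catch") {
      if (resp == "same_exemplar_key") "correct" else "category_confusion"
    } else {
      if (resp == "same_category_key") "correct" else "exemplar_confusion"
    }
  }
  is_catch <- trials$trial_type != "no_response"
  data.frame(run = trials$run, position = trials$position,
             trial_type = trials$trial_type, category = trials$category,
             i = ifelse(is_catch, i, NA), j = ifelse(is_catch, j, NA),
             outcome = outcome, rt = log$rt)
}

#' Per-level performance table
#'
#' Bins the scored same-category catch trials by the similarity level of
#' their exemplar pair under a partition (pairs excluded by the gap rule
#' are dropped) and tabulates the same-exemplar confusion rate and the mean
#' RT of correct responses per level.
#'
#' @param scored output of [score_oneback()].
#' @param partition level partition data.frame for the rating source
#'   (columns `category`, `i`, `j`, `level`).
#' @return data.frame with one row per level: `level`, `n_trials`,
#'   `error_rate`, `mean_rt`.
#' @export
performance_by_level <- function(scored, partition) {
  sc <- scored[scored$trial_type == "same_category_catch", ]
  lev <- partition$level[match(paste(sc$category, sc$i, sc$j),
                               paste(partition$category, partition$i,
                                     partition$j))]
  keep <- !is.na(lev) & lev != "excluded"
  sc <- sc[keep, ]; lev <- lev[keep]
  levels_order <- c("low", "medium", "high")
  out <- do.call(rbind, lapply(levels_order, function(L) {
    s <- sc[lev == L, ]
    data.frame(level = L, n_trials = nrow(s),
               error_rate = if (nrow(s)) mean(s$outcome == "exemplar_confusion")
                            else NA_real_,
               mean_rt = if (any(s$outcome == "correct"))
                 mean(s$rt[s$outcome == "correct"]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Similarity slope of a performance measure
#'
#' Ordinary least-squares slope of error rate or mean RT against the level
#' index (low = 1, medium = 2, high = 3): a positive slope means
#' performance degrades (or slows) as perceived similarity increases.
#'
#' @param perf performance table from [performance_by_level()].
#' @param measure `"error"` or `"rt"`.
#' @return slope per level step, or `NA` (with a warning) when a level has
#'   no trials.
#' @export
similarity_slope <- function(perf, measure = c("error", "rt")) {
  measure <- match.arg(measure)
  y <- if (measure == "error") perf$error_rate else perf$mean_rt
  x <- match(perf$level, c("low", "medium", "high"))
  if (anyNA(y) || any(perf$n_trials == 0)) {
    warning("empty similarity level; slope undefined for this observer")
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Own-versus-other similarity slopes across a cohort
#'
#' For every observer, computes the similarity slope of error rate and RT
#' when their catch trials are binned by their OWN level partition, and the
#' average slope when re-binned by each OTHER observer's partition (n - 1
#' iterations, then averaged). A paired t-test compares own against
#' other-mean slopes across observers; larger own slopes indicate that task
#' performance tracks the observer's own perceived similarity structure
#' specifically.
#'
#' @param scored_list list of scored logs (one per observer, from
#'   [score_oneback()]).
#' @param partitions list of level partitions, one per observer, same
#'   order.
#' @return list with `slopes` (data.frame: `observer`, `measure`, `own`,
#'   `other_mean`, `n_iterations`) and `tests` (data.frame per measure:
#'   paired `t`, `df`, `p`).
#' @export
own_vs_other <- function(scored_list, partitions) {
  n <- length(scored_list)
  if (n < 3L) stop("own-vs-other comparison needs at least 3 observers")
  if (length(partitions) != n)
    stop("need one partition per observer")
  slope_of <- function(o, p, measure)
    similarity_slope(performance_by_level(scored_list[[o]], partitions[[p]]),
                     measure)
  rows <- list()
  for (measure in c("error", "rt")) {
    own <- vapply(seq_len(n), function(o) slope_of(o, o, measure), 0)
    other <- vapply(seq_len(n), function(o)
      mean(vapply(setdiff(seq_len(n), o), function(p)
        slope_of(o, p, measure), 0)), 0)
    rows[[measure]] <- data.frame(observer = seq_len(n), measure = measure,
                                  own = own, other_mean = other,
                                  n_iterations = n - 1L)
  }
  slopes <- do.call(rbind, rows)
  rownames(slopes) <- NULL
  tests <- do.call(rbind, lapply(c("error", "rt"), function(measure) {
    s <- slopes[slopes$measure == measure, ]
    ok <- stats::complete.cases(s[, c("own", "other_mean")])
    if (sum(ok) < 3L)
      stop("fewer than 3 observers with defined slopes for ", measure)
    d <- s$own[ok] - s$other_mean[ok]
    if (stats::sd(d) == 0) {
      data.frame(measure = measure, mean_own = mean(s$own[ok]),
                 mean_other = mean(s$other_mean[ok]),
                 t = 0, df = sum(ok) - 1L, p = 1)
    } else {
      tt <- stats::t.test(s$own[ok], s$other_mean[ok], paired = TRUE,
                          alternative = "greater")
      data.frame(measure = measure, mean_own = mean(s$own[ok]),
                 mean_other = mean(s$other_mean[ok]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  list(slopes = slopes, tests = tests)
}
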