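#' Behavioural simulation parameters
#'
#' Governs the simulated observer's 1-back responses. Confusion probability
#' on same-category catch trials follows a logistic curve in the observer's
#' OWN perceived similarity of the repeated pair (similarity = 1 minus the
#' pair's dissimilarity percentile pooled over the observer's 60
#' within-category pairs), so more similar exemplars are more often
#' mistaken for exact repeats. Response times on catch trials grow linearly
#' with the same similarity.
#'
#' @param base_error confusion probability at mid similarity (s = 0.5).
#' @param error_slope logistic slope per unit similarity; 0 removes the
#'   similarity-error coupling.
#' @param base_rt mean RT (s) at mid similarity.
#' @param rt_slope RT increase (s) per unit similarity.
#' @param rt_sd Gaussian RT noise (s).
#' @param rt_min RT floor (s).
#' @param p_miss probability of no press on a catch trial.
#' @param exemplar_error probability of a same-category press on an exact
#'   repeat.
#' @param p_false_alarm probability of a press on a no-response trial.
#' @return list of class `behaviour_params`.
#' @export
behaviour_params <- function(base_error = 0.15, error_slope = 3,
                             base_rt = 0.75, rt_slope = 0.18, rt_sd = 0.15,
                             rt_min = 0.15, p_miss = 0.04,
                             exemplar_error = 0.04, p_false_alarm = 0.02) {
  structure(list(base_error = base_error, error_slope = error_slope,
                 base_rt = base_rt, rt_slope = rt_slope, rt_sd = rt_sd,
                 rt_min = rt_min, p_miss = p_miss,
                 exemplar_error = exemplar_error,
                 p_false_alarm = p_false_alarm),
            class = "behaviour_params")
}

#' Simulate 1-back responses for one observer
#'
#' @param gt a `study_ground_truth`.
#' @param observer observer index.
#' @param trials trial sequence from [generate_trial_sequence()].
#' @param params a [behaviour_params()].
#' @param seed RNG seed; derived from the study seed and observer by default.
#' @return data.frame aligned with `trials`: columns `run`, `position`,
#'   `response` (`none`, `same_exemplar_key`, `same_category_key`) and `rt`
#'   (seconds, `NA` when no response).
#' @export
simulate_behaviour <- function(gt, observer, trials,
                               params = behaviour_params(),
                               seed = derive_seed(gt$config$seed,
                                                  "behaviour", observer)) {
  set.seed(seed)
  td <- true_distances(gt, observer)
  sim <- 1 - to_percentiles(td$distance)
  sim_of <- function(category, a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    sim[match(paste(category, i, j), paste(td$category, td$i, td$j))]
  }
  n <- nrow(trials)
  response <- rep("none", n)
  rt <- rep(NA_real_, n)
  draw_rt <- function(s) {
    pmax(params$rt_min,
         params$base_rt + params$rt_slope * (s - 0.5) +
           stats::rnorm(length(s), sd = params$rt_sd))
  }
  prev_ex <- c(NA, trials$exemplar[-n])
  prev_run <- c(NA, trials$run[-n])
  for (t in seq_len(n)) {
    type <- trials$trial_type[t]
    if (type == "no_response") {
      if (stats::runif(1) < params$p_false_alarm) {
        response[t] <- sample(c("same_exemplar_key", "same_category_key"), 1L)
        rt[t] <- draw_rt(0.5)
      }
    } else if (stats::runif(1) >= params$p_miss) {
      if (type == "same_exemplar_catch") {
        response[t] <- if (stats::runif(1) < params$exemplar_error)
          "same_category_key" else "same_exemplar_key"
        rt[t] <- draw_rt(0.5)
      } else {  # same_category_catch
        s <- sim_of(trials$category[t], trials$exemplar[t], prev_ex[t])
        p_conf <- stats::plogis(stats::qlogis(params$base_error) +
                                  params$error_slope * (s - 0.5))
        response[t] <- if (stats::runif(1) < p_conf)
          "same_exemplar_key" else "same_category_key"
        rt[t] <- draw_rt(s)
      }
    }
  }
  data.frame(run = trials$run, position = trials$position,
             response = response, rt = rt)
}
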