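#' Simulate trial-wise voxel patterns for one observer and region
#'
#' Stands in for GLM-estimated single-trial activity patterns. Each
#' exemplar's signal vector mixes, with the region's weights, the shared
#' fine and coarse latent coordinates, the observer's own (perturbed)
#' latent coordinates, and the exemplar's intermediate feature vector; a
#' voxel read-out matrix
#' (fixed per observer x region, so patterns are stable across runs up to
#' noise) projects the mixture into voxel space; a fixed baseline
#' activation map of spread `sigma_baseline` common to every trial is
#' added, and i.i.d. Gaussian noise of spread `sigma_noise` per trial.
#'
#' @param gt a `study_ground_truth`.
#' @param observer observer index.
#' @param region a [region_spec()].
#' @param trials trial sequence from [generate_trial_sequence()].
#' @param seed RNG seed; derived from the study seed, observer and region
#'   name by default.
#' @return object of class `pattern_set`: list with `observer`, `region`,
#'   `patterns` (trials x voxels matrix) and `index` (the trial table).
#' @export
simulate_voxel_patterns <- function(gt, observer, region, trials,
                                    seed = derive_seed(gt$config$seed,
                                                       "patterns", observer,
                                                       region$name)) {
  stopifnot(inherits(region, "region_spec"))
  cfg <- gt$config
  n_cat <- cfg$n_categories
  n_ex <- cfg$n_exemplars_per_category
  d <- gt$latent_dim

  # exemplar signal matrix, rows indexed by (category - 1) * n_ex + exemplar
  U <- matrix(0, n_cat * n_ex, d)
  for (k in seq_len(n_cat)) {
    rows <- (k - 1L) * n_ex + seq_len(n_ex)
    U[rows, ] <- region$w_shared * shared_latent(gt, k) +
      region$w_coarse * coarse_latent(gt, k) +
      region$w_observer * observer_latent(gt, observer, k) +
      region$w_intermediate * gt$intermediate[k, , ]
  }
  set.seed(derive_seed(seed, "readout"))
  W <- matrix(stats::rnorm(region$n_voxels * d, sd = 1 / sqrt(d)),
              region$n_voxels, d)
  baseline <- stats::rnorm(region$n_voxels, sd = region$sigma_baseline)
  set.seed(derive_seed(seed, "noise"))
  ex_row <- (trials$category - 1L) * n_ex + trials$exemplar
  P <- U[ex_row, , drop = FALSE] %*% t(W)
  P <- sweep(P, 2L, baseline, "+")
  if (region$sigma_noise > 0)
    P <- P + matrix(stats::rnorm(length(P), sd = region$sigma_noise), nrow(P))
  structure(list(observer = observer, region = region$name,
                 patterns = P, index = trials),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: observer %s, region %s, %d trials x %d voxels\n",
              x$observer, x$region, nrow(x$patterns), ncol(x$patterns)))
  invisible(x)
}

#' Simulate a complete study cohort
#'
#' Runs the full generative model for every observer: arena arrangements,
#' 1-back trial sequences, behavioural logs and (optionally) voxel
#' patterns for each region. All randomness derives from `config$seed`.
#'
#' @param config a [study_config()].
#' @param regions named list of [region_spec()]s, or `NULL` to skip pattern
#'   simulation (behaviour-only cohorts are much cheaper).
#' @param latent_dim,sigma_observer,sigma_observer_fine,sigma_place,alpha_intermediate passed to
#'   [make_ground_truth()].
#' @param perf_params a [behaviour_params()].
#' @param with_behaviour logical; generate trial sequences + logs.
#' @return object of class `sim_study`: list with `config`, `ground_truth`,
#'   `arrangements` (one data.frame), `trials` and `behaviour` (lists by
#'   observer) and `patterns` (list by region of lists by observer).
#' @export
simulate_study <- function(config = study_config(), regions = default_regions(),
                           latent_dim = 8L, sigma_observer = 1.8,
                           sigma_observer_fine = sigma_observer / 3,
                           sigma_place = 0.02, alpha_intermediate = 0.1,
                           perf_params = behaviour_params(),
                           with_behaviour = TRUE) {
  gt <- make_ground_truth(config, latent_dim = latent_dim,
                          sigma_observer = sigma_observer,
                          sigma_observer_fine = sigma_observer_fine,
                          sigma_place = sigma_place,
                          alpha_intermediate = alpha_intermediate)
  obs <- seq_len(config$n_observers)
  arrangements <- do.call(rbind, lapply(obs, function(o)
    simulate_arrangements(gt, o)))
  trials <- behaviour <- NULL
  if (with_behaviour) {
    trials <- lapply(obs, function(o)
      generate_trial_sequence(config, seed = derive_seed(config$seed,
                                                         "trialseq", o)))
    behaviour <- lapply(obs, function(o)
      simulate_behaviour(gt, o, trials[[o]], params = perf_params))
  }
  patterns <- NULL
  if (!is.null(regions)) {
    if (is.null(trials))
      stop("pattern simulation needs trial sequences (with_behaviour = TRUE)")
    patterns <- lapply(regions, function(rg)
      lapply(obs, function(o) simulate_voxel_patterns(gt, o, rg, trials[[o]])))
    names(patterns) <- vapply(regions, `[[`, "", "name")
  }
  structure(list(config = config, ground_truth = gt,
                 arrangements = arrangements, trials = trials,
                 behaviour = behaviour, patterns = patterns,
                 regions = regions),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  print(x$config)
  cat(sprintf("  regions: %s\n",
              if (is.null(x$patterns)) "none (behaviour only)"
              else paste(names(x$patterns), collapse = ", ")))
  invisible(x)
}
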