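#' Study design configuration
#'
#' Describes the factorial design of the simulated experiment: a cohort of
#' observers who each arrange 4 exemplars from each of 10 object categories
#' in a circular arena, then perform a category-exemplar 1-back task in the
#' scanner. Per run every exemplar appears `reps_noresponse_per_run` times
#' as a no-response trial and `reps_catch_per_run` times as a catch trial
#' (an immediate repetition of the same exemplar, or of the same category
#' with a different exemplar). Under the defaults a run holds
#' 40 x 4 = 160 trials, 75% of them no-response.
#'
#' @param n_observers number of observers in the cohort.
#' @param n_categories object categories.
#' @param n_exemplars_per_category exemplars per category.
#' @param n_runs scanner runs.
#' @param reps_noresponse_per_run no-response presentations of each exemplar
#'   per run.
#' @param reps_catch_per_run catch presentations of each exemplar per run.
#' @param p_catch_exemplar probability that a catch trial is a same-exemplar
#'   (exact) repeat rather than a same-category repeat.
#' @param seed base seed from which all stage seeds are derived.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_observers = 23L, n_categories = 10L,
                         n_exemplars_per_category = 4L, n_runs = 8L,
                         reps_noresponse_per_run = 3L, reps_catch_per_run = 1L,
                         p_catch_exemplar = 0.5, seed = 1L) {
  counts <- c(n_observers = n_observers, n_categories = n_categories,
              n_exemplars_per_category = n_exemplars_per_category,
              n_runs = n_runs, reps_noresponse_per_run = reps_noresponse_per_run,
              reps_catch_per_run = reps_catch_per_run)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be integers >= 1")
  if (p_catch_exemplar < 0 || p_catch_exemplar > 1)
    stop("p_catch_exemplar must be in [0, 1]")
  cfg <- as.list(counts)
  cfg <- lapply(cfg, as.integer)
  cfg$p_catch_exemplar <- p_catch_exemplar
  cfg$seed <- as.integer(seed)
  cfg$trials_per_run <- with(cfg, n_categories * n_exemplars_per_category *
                               (reps_noresponse_per_run + reps_catch_per_run))
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Study design: %d observers, %d categories x %d exemplars, %d runs\n",
    "  per run: %d no-response + %d catch presentations per exemplar ",
    "(%d trials/run)\n"),
    x$n_observers, x$n_categories, x$n_exemplars_per_category, x$n_runs,
    x$reps_noresponse_per_run, x$reps_catch_per_run, x$trials_per_run))
  invisible(x)
}

#' Region-of-interest specification for pattern simulation
#'
#' A simulated ROI mixes four signal sources into its voxel patterns: the
#' fine-grained shared exemplar geometry all observers agree on
#' (`w_shared`), the COARSE shared geometry in which highly similar
#' exemplars are indistinguishable (`w_coarse`), the observer's own
#' perturbed fine geometry (`w_observer`), and intermediate visual-feature
#' coordinates of the kind a hierarchical Gabor model captures
#' (`w_intermediate`). Setting every weight to 0 yields a pure-noise
#' control region. The weights operationalize the representational
#' gradient from early visual cortex to medial temporal regions: posterior
#' regions resolve coarse distinctions only, while a PrC-like region holds
#' fine-grained, observer-specific conjunctions.
#'
#' @param name region label.
#' @param n_voxels voxels in the ROI.
#' @param w_shared,w_coarse,w_observer,w_intermediate non-negative mixing
#'   weights.
#' @param sigma_noise per-trial Gaussian pattern noise (signal units).
#' @param sigma_baseline spread of the fixed baseline activation map all
#'   trials share (per observer x region); exemplar-specific signals ride
#'   on this common stimulus-evoked topography, as in real ROI data.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(name, n_voxels = 60L, w_shared = 0, w_coarse = 0,
                        w_observer = 0, w_intermediate = 0, sigma_noise = 1,
                        sigma_baseline = 2) {
  w <- c(w_shared, w_coarse, w_observer, w_intermediate)
  if (any(w < 0) || sigma_noise < 0 || sigma_baseline < 0)
    stop("weights and noise must be >= 0")
  if (n_voxels < 2L) stop("a region needs at least 2 voxels")
  structure(list(name = name, n_voxels = as.integer(n_voxels),
                 w_shared = w_shared, w_coarse = w_coarse,
                 w_observer = w_observer,
                 w_intermediate = w_intermediate, sigma_noise = sigma_noise,
                 sigma_baseline = sigma_baseline),
            class = "region_spec")
}

#' Default simulated regions
#'
#' Four ROIs spanning the ventral-stream fidelity gradient the analysis is
#' designed to detect: an EVC-like region dominated by intermediate
#' image features, an LOC-like region carrying the shared component of
#' perceived similarity (plus intermediate features), a PrC-like region
#' dominated by the observer-specific component, and a pure-noise control.
#' The posterior regions carry coarse structure only, so fine-grained
#' (high-similarity) distinctions survive only in the PrC-like region.
#'
#' @return named list of `region_spec` objects.
#' @export
default_regions <- function() {
  list(
    `EVC-like`  = region_spec("EVC-like",  n_voxels = 60, w_coarse = 0.3,
                              w_intermediate = 1.0, sigma_noise = 3),
    `LOC-like`  = region_spec("LOC-like",  n_voxels = 60, w_coarse = 1.0,
                              w_intermediate = 0.5, sigma_noise = 3),
    `PrC-like`  = region_spec("PrC-like",  n_voxels = 60, w_shared = 0.3,
                              w_observer = 1.0, sigma_noise = 1.2),
    noise       = region_spec("noise", n_voxels = 60, sigma_noise = 1.0)
  )
}
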