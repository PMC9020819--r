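# Small simulated cohorts shared by tests; sizes chosen so each file stays
# fast while every pipeline stage still runs end to end.

small_config <- function(n_observers = 6L, n_runs = 4L, seed = 42L)
  study_config(n_observers = n_observers, n_runs = n_runs, seed = seed)

small_regions <- function(n_voxels = 24L) {
  list(
    signal = region_spec("signal", n_voxels = n_voxels, w_shared = 0.3,
                         w_observer = 1, sigma_noise = 1),
    noise = region_spec("noise", n_voxels = n_voxels, sigma_noise = 1)
  )
}

# behaviour-only cohort (no voxel patterns); memoized per test file
small_behaviour_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(small_config(), regions = NULL)
    cache
  }
})

behaviour_rdms_of <- function(study) {
  lapply(seq_len(study$config$n_observers), function(o)
    build_behaviour_rdm(
      study$arrangements[study$arrangements$observer == o, ],
      n_categories = study$config$n_categories))
}
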