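#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [pipeline_run()]:
#' the study design, the latent-structure parameters, the simulated
#' regions, and the analysis settings. Unknown keys are rejected.
#'
#' @param design named list of [study_config()] arguments.
#' @param structure named list: `latent_dim`, `sigma_observer`,
#'   `sigma_place`, `alpha_intermediate`.
#' @param regions named list of [region_spec()] argument lists, or `NULL`
#'   for the [default_regions()].
#' @param analysis named list: `min_gap`, `n_perm`, `alpha`,
#'   `run_decoding`, `decoding_levels`.
#' @param behaviour named list of [behaviour_params()] arguments.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = list(), structure = list(),
                            regions = NULL, analysis = list(),
                            behaviour = list()) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
  check_keys(design, names(formals(study_config)), "design")
  check_keys(structure,
             c("latent_dim", "sigma_observer", "sigma_place",
               "alpha_intermediate"), "structure")
  check_keys(analysis,
             c("min_gap", "n_perm", "alpha", "run_decoding",
               "decoding_levels"), "analysis")
  check_keys(behaviour, names(formals(behaviour_params)), "behaviour")
  analysis <- utils::modifyList(
    list(min_gap = 0.1, n_perm = 10000L, alpha = 0.05, run_decoding = FALSE,
         decoding_levels = c("low", "medium", "high")), analysis)
  if (!is.null(regions)) {
    for (rg in regions)
      check_keys(rg, names(formals(region_spec)), "regions entry")
  }
  structure(list(design = design, structure = structure, regions = regions,
                 analysis = analysis, behaviour = behaviour),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), c("design", "structure", "regions",
                                 "analysis", "behaviour"))
  if (length(extra))
    stop("unknown top-level key(s) in config: ", paste(extra, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes the stages in dependency order: simulate the cohort; build
#' behaviour RDMs and level partitions; build brain RDMs per region;
#' compute intersubject agreement, within-subject brain-behaviour
#' correlations (whole range and per level) with group inference, the
#' i-index with its subject-label permutation null per region, the 1-back
#' performance analyses, and (optionally) level-wise decoding. When
#' `out_dir` is given, all tabular artifacts, a JSON summary and a run
#' manifest are written there; outputs are byte-identical across reruns of
#' the same configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of results (`study`, `behaviour_rdms`, `partitions`,
#'   `brain_rdms`, `intersubject`, `rsa`, `i_index`, `performance`,
#'   `decoding`, `summary`).
#' @export
pipeline_run <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- do.call(study_config, config$design)
  regions <- if (is.null(config$regions)) default_regions() else
    lapply(config$regions, function(a) do.call(region_spec, a))
  names(regions) <- vapply(regions, `[[`, "", "name")
  an <- config$analysis

  study <- do.call(simulate_study, c(
    list(config = cfg, regions = regions,
         perf_params = do.call(behaviour_params, config$behaviour)),
    config$structure))
  obs <- seq_len(cfg$n_observers)

  behaviour_rdms <- lapply(obs, function(o)
    build_behaviour_rdm(study$arrangements[study$arrangements$observer == o, ],
                        n_categories = cfg$n_categories))
  partitions <- lapply(behaviour_rdms, stratify_levels, min_gap = an$min_gap)
  stacked_rdms <- do.call(rbind, behaviour_rdms)
  stacked_parts <- do.call(rbind, partitions)
  intersubject <- intersubject_correlation(stacked_rdms)

  brain_rdms <- lapply(names(regions), function(rg) {
    lapply(obs, function(o) {
      em <- exemplar_mean_patterns(study$patterns[[rg]][[o]])
      build_brain_rdm(em, observer = o, region = rg)
    })
  })
  names(brain_rdms) <- names(regions)

  subsets <- c("whole", "low", "medium", "high")
  n_family_whole <- length(regions)
  n_family_level <- length(regions) * 3L
  rsa_rows <- list(); i_list <- list()
  for (rg in names(regions)) {
    for (ss in subsets) {
      r <- vapply(obs, function(o)
        brain_behaviour_correlation(brain_rdms[[rg]][[o]],
                                    behaviour_rdms[[o]], subset = ss,
                                    partition = partitions[[o]])$r, 0)
      gi <- group_inference(r, n_tests = if (ss == "whole") n_family_whole
                                         else n_family_level)
      gi <- cbind(region = rg, subset = ss, gi)
      gi$significant <- gi$p_bonferroni < an$alpha
      rsa_rows[[paste(rg, ss)]] <- gi
    }
    M <- cross_correlation_matrix(brain_rdms[[rg]], behaviour_rdms,
                                  subset = "whole")
    ii <- permutation_null_i_index(M, n_perm = an$n_perm, seed = cfg$seed)
    i_list[[rg]] <- ii
  }
  rsa_table <- do.call(rbind, rsa_rows)
  rownames(rsa_table) <- NULL

  scored <- lapply(obs, function(o)
    score_oneback(study$behaviour[[o]], study$trials[[o]]))
  own_slopes_err <- vapply(obs, function(o)
    similarity_slope(performance_by_level(scored[[o]], partitions[[o]]),
                     "error"), 0)
  perf <- list(own_error_slopes = own_slopes_err,
               own_vs_other = own_vs_other(scored, partitions))

  decoding <- NULL
  if (isTRUE(an$run_decoding)) {
    decoding <- list()
    for (rg in names(regions)) {
      per_obs <- lapply(obs, function(o)
        level_decoding(study$patterns[[rg]][[o]], partitions[[o]],
                       levels = an$decoding_levels))
      by_level <- do.call(rbind, lapply(an$decoding_levels, function(L) {
        acc <- vapply(per_obs, function(x) {
          v <- x$by_level$accuracy[x$by_level$level == L]
          if (length(v)) v else NA_real_
        }, 0)
        gt <- decoding_group_test(acc[!is.na(acc)],
                                  n_tests = length(regions) *
                                    length(an$decoding_levels))
        cbind(region = rg, level = L, gt)
      }))
      decoding[[rg]] <- by_level
    }
  }

  summary <- list(
    design = unclass(cfg),
    intersubject_mean_r = intersubject$mean_r,
    rsa = rsa_table,
    i_index = lapply(i_list, function(x)
      list(mean_i = x$mean_i, p_perm = x$p_perm,
           sem_randomization = x$sem_randomization)),
    behaviour = perf$own_vs_other$tests)

  res <- list(study = study, behaviour_rdms = behaviour_rdms,
              partitions = partitions, brain_rdms = brain_rdms,
              intersubject = intersubject, rsa = rsa_table,
              i_index = i_list, performance = perf, decoding = decoding,
              summary = summary, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_arrangements_csv(res$study$arrangements,
                         file.path(out_dir, "arrangements.csv"))
  stacked <- do.call(rbind, res$partitions)
  write_rdm_csv(stacked, file.path(out_dir, "behaviour_rdms.csv"))
  brain_all <- do.call(rbind, lapply(res$brain_rdms, function(x)
    do.call(rbind, x)))
  write_rdm_csv(brain_all, file.path(out_dir, "brain_rdms.csv"))
  utils::write.csv(res$rsa, file.path(out_dir, "rsa_group_stats.csv"),
                   row.names = FALSE)
  if (!is.null(res$decoding))
    utils::write.csv(do.call(rbind, res$decoding),
                     file.path(out_dir, "decoding_group_stats.csv"),
                     row.names = FALSE)
  summary <- res$summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  manifest <- list(
    package = "idiorsa",
    version = as.character(utils::packageVersion("idiorsa")),
    config_hash = fnv1a(yaml::as.yaml(unclass(res$config))),
    seed = res$study$config$seed,
    stages = c("simulate", "behaviour-rdm", "brain-rdm", "rsa", "i-index",
               "behaviour", if (!is.null(res$decoding)) "decode"),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
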