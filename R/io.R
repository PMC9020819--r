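#' Write / read a long-form RDM CSV
#'
#' One observation per row with the fixed header
#' `observer,region,category,exemplar_i,exemplar_j,raw,percentile,level`;
#' `region` and `level` may be empty. Numeric columns are written with full
#' precision so a round trip is lossless to 1e-12.
#'
#' @param rdm RDM data.frame (columns `observer`, `category`, `i`, `j`,
#'   `raw`, `percentile`, optional `region` and `level`).
#' @param path file path.
#' @export
write_rdm_csv <- function(rdm, path) {
  out <- data.frame(
    observer = rdm$observer,
    region = if ("region" %in% names(rdm)) rdm$region else NA,
    category = rdm$category, exemplar_i = rdm$i, exemplar_j = rdm$j,
    raw = sprintf("%.17g", rdm$raw),
    percentile = sprintf("%.17g", rdm$percentile),
    level = if ("level" %in% names(rdm)) rdm$level else NA)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @return `read_rdm_csv`: the RDM data.frame (with `region`/`level`
#'   columns when present in the file).
#' @export
read_rdm_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- gsub('"', "", header)
  expected <- c("observer", "region", "category", "exemplar_i", "exemplar_j",
                "raw", "percentile", "level")
  if (!identical(header, expected))
    stop("malformed RDM CSV header in ", path, ": expected '",
         paste(expected, collapse = ","), "'")
  df <- utils::read.csv(path, colClasses = c(
    observer = "character", region = "character", category = "integer",
    exemplar_i = "integer", exemplar_j = "integer", raw = "numeric",
    percentile = "numeric", level = "character"), na.strings = "")
  bad <- which(!stats::complete.cases(df[, c("category", "exemplar_i",
                                             "exemplar_j", "raw",
                                             "percentile")]))
  if (length(bad))
    stop("malformed RDM CSV row(s) in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))
  out <- data.frame(observer = type.convert(df$observer, as.is = TRUE),
                    category = df$category, i = df$exemplar_i,
                    j = df$exemplar_j, raw = df$raw,
                    percentile = df$percentile)
  if (any(nzchar(df$region) & !is.na(df$region))) out$region <- df$region
  if (any(nzchar(df$level) & !is.na(df$level))) out$level <- df$level
  out
}

#' Arrangements, trials and behaviour CSV round trips
#'
#' Tidy per-row writers/readers for the three tabular artifacts of a
#' simulated (or imported) study.
#'
#' @param x the data.frame to write.
#' @param path file path.
#' @name study_csv
#' @export
write_arrangements_csv <- function(x, path) {
  stopifnot(all(c("observer", "category", "exemplar", "x", "y") %in% names(x)))
  out <- x[, c("observer", "category", "exemplar", "x", "y")]
  out$x <- sprintf("%.17g", out$x); out$y <- sprintf("%.17g", out$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_csv
#' @export
read_arrangements_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("observer", "category", "exemplar", "x", "y")
  if (!all(need %in% names(df)))
    stop("arrangements CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname study_csv
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(x[, c("run", "position", "category", "exemplar",
                         "trial_type")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname study_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("run", "position", "category", "exemplar", "trial_type")
  if (!all(need %in% names(df)))
    stop("trials CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname study_csv
#' @export
write_behaviour_csv <- function(x, path) {
  out <- x[, c("run", "position", "response", "rt")]
  out$rt <- ifelse(is.na(out$rt), "", sprintf("%.17g", out$rt))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname study_csv
#' @export
read_behaviour_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  df$rt <- as.numeric(df$rt)
  need <- c("run", "position", "response", "rt")
  if (!all(need %in% names(df)))
    stop("behaviour CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write / read a pattern set as a portable text container
#'
#' The voxel matrix goes to `<stem>.csv` (one row per trial, columns
#' `v1..vK` after the trial index columns) and a JSON sidecar
#' `<stem>.json` records observer, region, dimensions and column layout.
#'
#' @param ps a `pattern_set`.
#' @param stem file stem (without extension).
#' @export
write_pattern_set <- function(ps, stem) {
  idx <- ps$index
  mat <- as.data.frame(ps$patterns)
  names(mat) <- paste0("v", seq_len(ncol(mat)))
  for (cn in names(mat)) mat[[cn]] <- sprintf("%.17g", as.numeric(mat[[cn]]))
  utils::write.csv(cbind(idx, mat), paste0(stem, ".csv"), row.names = FALSE,
                   quote = FALSE)
  sidecar <- list(observer = ps$observer, region = ps$region,
                  n_trials = nrow(ps$patterns), n_voxels = ncol(ps$patterns),
                  index_columns = names(idx))
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(stem) {
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(stem, ".csv"))
  vcols <- paste0("v", seq_len(sidecar$n_voxels))
  if (!all(vcols %in% names(df)))
    stop("pattern CSV does not match its JSON sidecar (", stem, ")")
  structure(list(observer = sidecar$observer, region = sidecar$region,
                 patterns = as.matrix(df[, vcols]),
                 index = df[, sidecar$index_columns, drop = FALSE]),
            class = "pattern_set")
}

#' Extract a pattern set from a 4-D NIfTI volume and ROI mask
#'
#' Optional import path for real data: reads a 4-D volume (one 3-D frame
#' per trial) and a binary ROI mask of matching grid, and returns the
#' masked voxels per trial as a `pattern_set`. Requires the RNifti package.
#'
#' @param volume_path 4-D NIfTI file, one volume per trial.
#' @param mask_path 3-D NIfTI binary mask.
#' @param index data.frame with one row per trial (`run`, `category`,
#'   `exemplar`, `trial_type`, ...).
#' @param observer,region labels for the resulting set.
#' @return a `pattern_set`.
#' @export
patterns_from_nifti <- function(volume_path, mask_path, index,
                                observer = NA, region = NA) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("patterns_from_nifti requires the RNifti package")
  vol <- RNifti::readNifti(volume_path)
  mask <- RNifti::readNifti(mask_path)
  if (length(dim(vol)) != 4L)
    stop("expected a 4-D volume (x, y, z, trial)")
  if (!identical(dim(vol)[1:3], dim(mask)[1:3]))
    stop("mask grid does not match the volume grid")
  keep <- which(mask != 0)
  n_t <- dim(vol)[4L]
  if (nrow(index) != n_t)
    stop("index has ", nrow(index), " rows but volume has ", n_t, " frames")
  flat <- matrix(vol, prod(dim(vol)[1:3]), n_t)
  structure(list(observer = observer, region = region,
                 patterns = t(flat[keep, , drop = FALSE]), index = index),
            class = "pattern_set")
}
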