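.cohort_cols <- c("subject_id", "label", "finding", "stage", "histology",
                  "gender", "age", "pack_years", "match_id")

#' Write / read a cohort CSV
#'
#' Cohort interchange format: UTF-8 comma-separated with a header row, one
#' row per subject — `subject_id`, `label`, `finding`, `stage`, `histology`,
#' `gender`, `age`, `pack_years`, `match_id`, then one concentration column
#' per marker ("." decimal point). `read_cohort()` canonicalizes marker
#' headers via [canonical_marker_names()], validates types and positivity of
#' concentrations, and reports the offending row on failure.
#'
#' @param cohort Cohort `data.frame` (see [generate_cohort()]).
#' @param path CSV file path.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: the cohort
#'   `data.frame`, marker columns canonicalized.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(.cohort_cols, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  markers <- setdiff(names(cohort), .cohort_cols)
  write.csv(cohort[, c(.cohort_cols, markers)], path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 check.names = FALSE)
  miss <- setdiff(.cohort_cols, names(df))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1]
    stop("duplicate subject_id '", dup, "'")
  }
  bad_label <- which(!df$label %in% c("case", "control"))
  if (length(bad_label))
    stop("invalid label at row ", bad_label[1], ": '", df$label[bad_label[1]], "'")
  markers <- setdiff(names(df), .cohort_cols)
  names(df)[match(markers, names(df))] <- canonical_marker_names(markers)
  markers <- canonical_marker_names(markers)
  for (mk in markers) {
    v <- suppressWarnings(as.numeric(df[[mk]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad))
      stop("marker '", mk, "': nonnumeric or nonpositive level at row ",
           bad[1])
    df[[mk]] <- v
  }
  df$age <- as.numeric(df$age)
  df$pack_years <- as.numeric(df$pack_years)
  df
}

#' Write / read a clotting-time series CSV
#'
#' Long format: `donor`, `marker`, `time_h`, `level`, one row per
#' measurement.
#'
#' @param series Clotting series `data.frame` (see
#'   [generate_clotting_series()]).
#' @param path CSV file path.
#' @return `write_clotting_series()`: `path`, invisibly;
#'   `read_clotting_series()`: the series `data.frame`.
#' @export
write_clotting_series <- function(series, path) {
  req <- c("donor", "marker", "time_h", "level")
  miss <- setdiff(req, names(series))
  if (length(miss)) stop("series lacks column(s): ", paste(miss, collapse = ", "))
  write.csv(series[, req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clotting_series
#' @export
read_clotting_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("donor", "marker", "time_h", "level")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("series file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$marker <- canonical_marker_names(df$marker)
  df
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline run. Input paths are
#' optional: a stage whose input path is `NULL` generates its input
#' synthetically (via [default_marker_specs()] and the study-sized cohort
#' configurations) from the run seed.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param preanalytical_path,training_path,validation_path Optional input
#'   CSVs (clotting series; training cohort; validation cohort).
#' @param alpha Lasso share of the elasticnet penalty (default 0.95).
#' @param B_select,B_validate Bootstrap iteration counts for penalty
#'   selection and internal validation (study default 10,000 each).
#' @param n_lambda,lambda_min_ratio Penalty grid parameters.
#' @param stability_threshold Deselection cutoff of the stability screen.
#' @param log_transform,standardize Preprocessing toggles.
#' @param seed Integer seed driving every stochastic step.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       preanalytical_path = NULL, training_path = NULL,
                       validation_path = NULL,
                       alpha = 0.95, B_select = 10000, B_validate = 10000,
                       n_lambda = 100, lambda_min_ratio = 1e-3,
                       stability_threshold = 0.20,
                       log_transform = TRUE, standardize = TRUE,
                       seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(alpha > 0, alpha <= 1, B_select >= 1, B_validate >= 2,
            n_lambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            stability_threshold >= 0)
  structure(
    list(output_dir = output_dir,
         preanalytical_path = preanalytical_path,
         training_path = training_path,
         validation_path = validation_path,
         alpha = alpha, B_select = as.integer(B_select),
         B_validate = as.integer(B_validate),
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         stability_threshold = stability_threshold,
         log_transform = log_transform, standardize = standardize,
         seed = as.integer(seed), log_level = log_level),
    class = "run_config")
}

#' Round-trip a run configuration through YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly; `read_run_config()`: the
#'   restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
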