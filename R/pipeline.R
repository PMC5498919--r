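pipe_log <- function(config, stage, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

run_stage <- function(config, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("incomplete at stage: ", stage),
               file.path(config$output_dir, "_INCOMPLETE"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screen-train-validate pipeline
#'
#' Sequences the workflow's three stages from one configuration and seed:
#' (1) the pre-analytical stability screen deselects clotting-sensitive
#' markers; (2) the training stage preprocesses the retained markers, selects
#' the elasticnet penalty by stratified bootstrap out-of-bag AUC, freezes the
#' final model, and internally validates it by bootstrap; (3) the validation
#' stage re-reads the frozen model (verified by checksum) and scores the
#' independent cohort with subgroup analyses and train-versus-validation AUC
#' deltas. Inputs not supplied as files are generated synthetically at the
#' study sizes from the run seed. All artifacts are written under
#' `config$output_dir` with the configuration and seed embedded; two runs
#' with the same configuration produce byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of each stage:
#'   `stability_report`, `retained`, `selection`, `model`, `training_report`,
#'   `bootstrap_validation`, `validation_report`, `delta_table`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config$output_dir, "_INCOMPLETE"))
  out <- function(f) file.path(config$output_dir, f)
  write_run_config(config, out("config_used.yaml"))
  pipe_log(config, "setup", seed = config$seed, alpha = config$alpha,
           B_select = config$B_select, B_validate = config$B_validate,
           n_lambda = config$n_lambda,
           lambda_min_ratio = config$lambda_min_ratio,
           stability_threshold = config$stability_threshold,
           log_transform = config$log_transform,
           standardize = config$standardize)
  specs <- default_marker_specs()

  # stage 1: pre-analytical stability screen
  screen <- run_stage(config, "screen", {
    series <- if (!is.null(config$preanalytical_path)) {
      read_clotting_series(config$preanalytical_path)
    } else {
      s <- generate_clotting_series(specs, n_donors = 6, noise_sd = 0.05,
                                    seed = config$seed)
      write_clotting_series(s, out("clotting_series.csv"))
      s
    }
    report <- relative_change(series)
    retained <- deselect_markers(report, config$stability_threshold)
    write.csv(as.data.frame(report), out("stability_report.csv"),
              row.names = FALSE)
    writeLines(retained, out("retained_markers.txt"))
    pipe_log(config, "screen", markers = nrow(report),
             retained = length(retained),
             deselected = paste(attr(retained, "deselected"), collapse = ","))
    list(report = report, retained = retained)
  })

  # stage 2: panel training on the retained markers
  train <- run_stage(config, "train", {
    cohort <- if (!is.null(config$training_path)) {
      read_cohort(config$training_path)
    } else {
      co <- generate_cohort(training_config(seed = config$seed + 1L), specs)
      write_cohort(co, out("training_cohort.csv"))
      co
    }
    markers <- intersect(screen$retained, names(cohort))
    if (length(markers) == 0L) stop("no retained marker present in the training cohort")
    fm <- feature_matrix(cohort[, markers, drop = FALSE], cohort$label,
                         log_transform = config$log_transform,
                         standardize = config$standardize)
    sel <- select_penalty(fm, alpha = config$alpha, B = config$B_select,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio,
                          seed = config$seed + 2L)
    write.csv(data.frame(lambda = sel$lambdas,
                         mean_oob_auc = sel$mean_oob_auc,
                         n_valid = sel$n_valid),
              out("selection_curve.csv"), row.names = FALSE)
    model <- final_fit(fm, sel)
    write_model(model, out("model.txt"))
    score <- enet_score(model, cohort)
    apparent <- delong_summary(score[cohort$label == "case"],
                               score[cohort$label == "control"])
    boot <- bootstrap_validate(fm, sel, B = config$B_validate,
                               seed = config$seed + 3L)
    train_report <- data.frame(
      quantity = c("apparent_auc", "apparent_ci_low", "apparent_ci_high",
                   "bootstrap_auc", "bootstrap_ci_low", "bootstrap_ci_high",
                   "selected_lambda", "panel_size"),
      value = c(apparent$auc, apparent$ci_low, apparent$ci_high,
                boot$point_auc, boot$ci_low, boot$ci_high,
                sel$selected_lambda, length(panel_markers(model))))
    write.csv(train_report, out("training_report.csv"), row.names = FALSE)
    writeLines(panel_markers(model), out("panel_markers.txt"))
    pipe_log(config, "train", n = nrow(cohort), B = config$B_select,
             selected_lambda = signif(sel$selected_lambda, 4),
             panel = paste(panel_markers(model), collapse = ","),
             apparent_auc = round(apparent$auc, 3),
             bootstrap_auc = round(boot$point_auc, 3))
    list(cohort = cohort, fm = fm, selection = sel, model = model,
         apparent = apparent, boot = boot, markers = markers,
         model_hash = model_checksum(out("model.txt")))
  })

  # stage 3: blinded validation of the frozen model
  valid <- run_stage(config, "validate", {
    model_path <- out("model.txt")
    if (!identical(model_checksum(model_path), train$model_hash))
      stop("frozen model file changed between training and validation")
    model <- read_model(model_path)
    cohort <- if (!is.null(config$validation_path)) {
      read_cohort(config$validation_path)
    } else {
      co <- rbind(
        generate_cohort(validation_config("nodule", seed = config$seed + 4L), specs),
        generate_cohort(validation_config("mass", seed = config$seed + 5L), specs),
        generate_cohort(validation_config("other", seed = config$seed + 6L), specs))
      co$subject_id <- sprintf("v_%04d", seq_len(nrow(co)))
      co$match_id <- paste0(co$finding, "_", co$match_id)
      write_cohort(co, out("validation_cohort.csv"))
      co
    }
    report <- validate_cohort(model, cohort, model_path = model_path)
    write.csv(report$analyses, out("validation_report.csv"),
              row.names = FALSE)
    write.csv(report$score_summary, out("score_summary.csv"),
              row.names = FALSE)

    # per-marker attenuation: training vs validation single-marker AUCs,
    # within the nodule stratum (or the whole cohort if unstratified)
    tr_co <- train$cohort
    nod <- !is.na(cohort$finding) & cohort$finding == "nodule"
    va_co <- if (any(nod)) cohort[nod, , drop = FALSE] else cohort
    mk_auc <- function(co, mk) empirical_auc(co[[mk]][co$label == "case"],
                                             co[[mk]][co$label == "control"])
    common <- intersect(train$markers, names(va_co))
    deltas <- auc_delta_table(
      stats::setNames(vapply(common, mk_auc, numeric(1), co = tr_co), common),
      stats::setNames(vapply(common, mk_auc, numeric(1), co = va_co), common))
    write.csv(deltas, out("auc_delta_table.csv"), row.names = FALSE)
    pipe_log(config, "validate", n = nrow(cohort),
             analyses = nrow(report$analyses),
             mean_marker_delta = round(attr(deltas, "mean_delta"), 3))
    list(cohort = cohort, report = report, deltas = deltas,
         model_hash = report$model_hash)
  })

  summary <- list(
    seed = config$seed,
    panel = panel_markers(train$model),
    selected_lambda = train$selection$selected_lambda,
    apparent_auc = train$apparent$auc,
    bootstrap_auc = train$boot$point_auc,
    model_md5 = valid$model_hash,
    mean_marker_auc_delta = attr(valid$deltas, "mean_delta"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    stability_report = screen$report, retained = screen$retained,
    selection = train$selection, model = train$model,
    training_report = list(apparent = train$apparent, boot = train$boot),
    bootstrap_validation = train$boot,
    validation_report = valid$report, delta_table = valid$deltas,
    paths = list(output_dir = config$output_dir)))
}
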