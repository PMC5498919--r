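#' Define a validation subgroup
#'
#' A subgroup analysis compares a filtered subset of cases against a
#' (possibly filtered) control group. Filters are vectors of allowed values;
#' `NULL` means no restriction. Stage and histology filters apply to cases
#' only (controls carry neither).
#'
#' @param name Analysis label.
#' @param case_stage,case_histology,case_finding Allowed values for cases.
#' @param control_finding Allowed findings for controls.
#' @return Object of class `subgroup_definition`.
#' @export
subgroup_definition <- function(name, case_stage = NULL,
                                case_histology = NULL, case_finding = NULL,
                                control_finding = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(
    list(name = name, case_stage = case_stage,
         case_histology = case_histology, case_finding = case_finding,
         control_finding = control_finding),
    class = "subgroup_definition")
}

#' Canonical stage / histology / finding subgroup set
#'
#' Builds the standard subgroup panel for a validation cohort: each tumor
#' stage (IA, IB, II, III, IV) among nodule cases versus all benign-nodule
#' controls; adenocarcinoma, squamous cell, and all remaining histologies
#' among nodule cases versus benign-nodule controls; and each radiographic
#' finding stratum (nodule, mass, other) versus its own matched controls —
#' the matched design is respected by never mixing controls across finding
#' strata. Only subgroups represented in the cohort are emitted; an empty
#' cohort yields an empty list.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @return List of [subgroup_definition()] objects.
#' @export
canonical_subgroups <- function(cohort) {
  if (nrow(cohort) == 0L) return(list())
  defs <- list()
  is_case <- cohort$label == "case"
  nodule_cases <- is_case & !is.na(cohort$finding) &
    cohort$finding == "nodule"
  for (st in c("IA", "IB", "II", "III", "IV")) {
    if (any(nodule_cases & !is.na(cohort$stage) & cohort$stage == st))
      defs <- c(defs, list(subgroup_definition(
        paste0("stage ", st, " (nodule)"), case_stage = st,
        case_finding = "nodule", control_finding = "nodule")))
  }
  hist <- cohort$histology[nodule_cases]
  main <- c(adenocarcinoma = "Adenocarcinoma", `squamous cell` = "Squamous cell")
  for (i in seq_along(main)) {
    if (any(hist == main[i], na.rm = TRUE))
      defs <- c(defs, list(subgroup_definition(
        paste0(names(main)[i], " (nodule)"), case_histology = main[i],
        case_finding = "nodule", control_finding = "nodule")))
  }
  others <- setdiff(unique(hist[!is.na(hist)]), main)
  if (length(others))
    defs <- c(defs, list(subgroup_definition(
      "other histology (nodule)", case_histology = others,
      case_finding = "nodule", control_finding = "nodule")))
  for (fd in c("nodule", "mass", "other")) {
    if (any(is_case & !is.na(cohort$finding) & cohort$finding == fd))
      defs <- c(defs, list(subgroup_definition(
        paste0("finding: ", fd), case_finding = fd, control_finding = fd)))
  }
  defs
}

subgroup_rows <- function(def, cohort) {
  keep_case <- cohort$label == "case"
  if (!is.null(def$case_finding))
    keep_case <- keep_case & !is.na(cohort$finding) &
      cohort$finding %in% def$case_finding
  if (!is.null(def$case_stage))
    keep_case <- keep_case & !is.na(cohort$stage) &
      cohort$stage %in% def$case_stage
  if (!is.null(def$case_histology))
    keep_case <- keep_case & !is.na(cohort$histology) &
      cohort$histology %in% def$case_histology
  keep_ctrl <- cohort$label == "control"
  if (!is.null(def$control_finding))
    keep_ctrl <- keep_ctrl & !is.na(cohort$finding) &
      cohort$finding %in% def$control_finding
  list(cases = which(keep_case), controls = which(keep_ctrl))
}

roc_row <- function(name, finding, case_scores, control_scores) {
  m <- length(case_scores); n <- length(control_scores)
  if (m < 2L || n < 2L) {
    return(data.frame(
      analysis = name, finding = finding %||% NA_character_,
      n_cases = m, n_controls = n, auc = NA_real_, var_auc = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
      flagged = TRUE, stringsAsFactors = FALSE))
  }
  s <- delong_summary(case_scores, control_scores)
  data.frame(
    analysis = name, finding = finding %||% NA_character_,
    n_cases = m, n_controls = n, auc = s$auc, var_auc = s$var_auc,
    ci_low = s$ci_low, ci_high = s$ci_high, p_value = s$p_value,
    flagged = FALSE, stringsAsFactors = FALSE)
}

#' Score a frozen model on a blinded validation cohort
#'
#' Applies a trained, frozen classifier to an independent matched
#' case-control cohort and produces the validation result set: the panel's
#' ROC summary per radiographic-finding stratum, single-marker ROC summaries
#' (using the raw marker concentration as the score — the AUC is rank-based,
#' so no refit is involved), and the requested subgroup analyses. Subgroup
#' case sets are compared against the full control group of the relevant
#' finding stratum. Controls are never mixed across finding strata. The
#' model is read-only throughout; the checksum of its frozen representation
#' is recorded for the blinding audit trail.
#'
#' @param model A frozen `enet_model`.
#' @param cohort Validation cohort `data.frame` with both classes.
#' @param subgroups List of [subgroup_definition()]s; defaults to
#'   [canonical_subgroups()] of the cohort.
#' @param model_path Optional path of the frozen model file; when given, its
#'   checksum is recorded, otherwise the checksum of an equivalent serialized
#'   copy is used.
#' @return Object of class `validation_report`: `analyses` (one row per
#'   analysis: name, stratum, class sizes, AUC, DeLong variance, CI, p,
#'   flag), `score_summary` (per stratum and class: n, mean, sd, quartiles of
#'   the panel score), `panel`, `model_hash`.
#' @export
validate_cohort <- function(model, cohort, subgroups = NULL,
                            model_path = NULL) {
  stopifnot(inherits(model, "enet_model"))
  if (!all(c("case", "control") %in% cohort$label))
    stop("validation cohort must contain both classes")
  if (is.null(subgroups)) subgroups <- canonical_subgroups(cohort)
  if (is.null(model_path)) {
    model_path <- tempfile(fileext = ".txt")
    write_model(model, model_path)
    on.exit(unlink(model_path), add = TRUE)
  }
  hash <- model_checksum(model_path)

  score <- enet_score(model, cohort)
  is_case <- cohort$label == "case"
  strata <- unique(cohort$finding[!is.na(cohort$finding)])
  if (length(strata) == 0L) strata <- NA_character_

  rows <- list()
  for (fd in strata) {
    in_stratum <- if (is.na(fd)) rep(TRUE, nrow(cohort))
                  else !is.na(cohort$finding) & cohort$finding == fd
    label <- if (is.na(fd)) "all" else fd
    rows[[length(rows) + 1L]] <- roc_row(
      paste0("PNC (", label, ")"), fd,
      score[in_stratum & is_case], score[in_stratum & !is_case])
    for (mk in model$marker_names) {
      lev <- cohort[[mk]]
      if (is.null(lev)) next
      rows[[length(rows) + 1L]] <- roc_row(
        paste0(mk, " (", label, ")"), fd,
        lev[in_stratum & is_case], lev[in_stratum & !is_case])
    }
  }
  for (def in subgroups) {
    idx <- subgroup_rows(def, cohort)
    rows[[length(rows) + 1L]] <- roc_row(
      def$name, def$case_finding %||% NA_character_,
      score[idx$cases], score[idx$controls])
  }
  analyses <- do.call(rbind, rows)
  rownames(analyses) <- NULL

  grp <- interaction(ifelse(is.na(cohort$finding), "all", cohort$finding),
                     cohort$label, sep = "/", drop = TRUE)
  score_summary <- do.call(rbind, lapply(levels(grp), function(g) {
    s <- score[grp == g]
    q <- unname(quantile(s, c(0.25, 0.5, 0.75)))
    data.frame(group = g, n = length(s), mean = mean(s), sd = sd(s),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))

  structure(
    list(analyses = analyses, score_summary = score_summary,
         panel = panel_markers(model), model_hash = hash),
    class = "validation_report")
}

#' Training-versus-validation AUC differences
#'
#' Per-marker difference `AUC_train - AUC_valid` and its mean over the
#' supplied markers, quantifying the attenuation of marker performance
#' between the training and blinded validation studies.
#'
#' @param train_aucs,valid_aucs Named numeric vectors of AUCs (same marker
#'   set), or data.frames with columns `marker` and `auc`.
#' @return `data.frame` with `marker`, `auc_train`, `auc_valid`, `delta`,
#'   plus the mean delta as attribute `"mean_delta"`.
#' @export
auc_delta_table <- function(train_aucs, valid_aucs) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$auc, x$marker) else x
  }
  tr <- as_named(train_aucs); va <- as_named(valid_aucs)
  if (is.null(names(tr)) || is.null(names(va)))
    stop("AUC vectors must be named by marker")
  if (!setequal(names(tr), names(va)))
    stop("marker sets differ: ",
         paste(union(setdiff(names(tr), names(va)),
                     setdiff(names(va), names(tr))), collapse = ", "))
  va <- va[names(tr)]
  out <- data.frame(marker = names(tr), auc_train = unname(tr),
                    auc_valid = unname(va), delta = unname(tr - va),
                    stringsAsFactors = FALSE)
  attr(out, "mean_delta") <- mean(out$delta)
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> panel: %s (model md5 %s)\n",
              paste(x$panel, collapse = ", "), substr(x$model_hash, 1, 8)))
  df <- x$analyses
  df$auc <- sprintf("%.3f", df$auc)
  df$ci <- sprintf("[%.3f-%.3f]", df$ci_low, df$ci_high)
  df$p_value <- format.pval(df$p_value, digits = 3)
  print(df[, c("analysis", "n_cases", "n_controls", "auc", "ci", "p_value")],
        row.names = FALSE)
  invisible(x)
}
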