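#' Empirical AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half: the mean over all case-control pairs
#' of `1[case > control] + 0.5 * 1[case == control]`. Computed via midranks,
#' which is exactly the pairwise mean.
#'
#' @param case_scores,control_scores Numeric score vectors (higher = more
#'   case-like); each non-empty.
#' @return The AUC in `[0, 1]`.
#' @export
empirical_auc <- function(case_scores, control_scores) {
  m <- length(case_scores); n <- length(control_scores)
  if (m == 0L || n == 0L) stop("both score groups must be non-empty")
  if (anyNA(case_scores) || anyNA(control_scores)) stop("scores contain NA")
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# Placement values: for each case the fraction of controls it outscores
# (ties half), and symmetrically for controls. Row/column means of the
# pairwise indicator matrix.
placement_values <- function(case_scores, control_scores) {
  pc <- vapply(case_scores, function(s)
    (sum(control_scores < s) + 0.5 * sum(control_scores == s)) /
      length(control_scores), numeric(1))
  pk <- vapply(control_scores, function(s)
    (sum(case_scores > s) + 0.5 * sum(case_scores == s)) /
      length(case_scores), numeric(1))
  list(cases = pc, controls = pk)
}

#' DeLong ROC summary
#'
#' Empirical AUC with the DeLong nonparametric variance estimate from
#' placement values: `var_auc = var(placements_cases)/m +
#' var(placements_controls)/n` (sample variances). The confidence interval is
#' the untransformed Wald interval `auc +/- z * sqrt(var_auc)`, truncated to
#' `[0, 1]`; the p-value tests AUC = 0.5 (two-sided), by default as a DeLong
#' z-test, optionally as a Wilcoxon rank-sum test.
#'
#' @param case_scores,control_scores Numeric score vectors, at least two per
#'   group for a finite variance estimate.
#' @param level Confidence level (default 0.95).
#' @param p_method `"delong"` (z-test against 0.5) or `"wilcoxon"`
#'   (Mann-Whitney rank-sum test).
#' @return An object of class `roc_summary`: `auc`, `var_auc`, `ci_low`,
#'   `ci_high`, `p_value`, `n_cases`, `n_controls`, `level`.
#' @export
delong_summary <- function(case_scores, control_scores, level = 0.95,
                           p_method = c("delong", "wilcoxon")) {
  p_method <- match.arg(p_method)
  m <- length(case_scores); n <- length(control_scores)
  if (m < 2L || n < 2L)
    stop("need at least 2 scores per group for a DeLong variance")
  auc <- empirical_auc(case_scores, control_scores)
  pl <- placement_values(case_scores, control_scores)
  v <- var(pl$cases) / m + var(pl$controls) / n
  se <- sqrt(v)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (p_method == "wilcoxon") {
    suppressWarnings(wilcox.test(case_scores, control_scores)$p.value)
  } else if (se > 0) {
    2 * pnorm(-abs((auc - 0.5) / se))
  } else if (auc == 0.5) 1 else 0  # degenerate: no sampling variability
  structure(
    list(auc = auc, var_auc = v, ci_low = ci[1], ci_high = ci[2],
         p_value = p, n_cases = m, n_controls = n, level = level,
         p_method = p_method),
    class = "roc_summary")
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects. The
#' variance of the AUC difference accounts for their correlation through the
#' covariance of paired placement values:
#' `var(d) = var_a + var_b - 2 * (cov(P_cases_a, P_cases_b)/m +
#' cov(P_controls_a, P_controls_b)/n)`.
#'
#' @param scores_a,scores_b Numeric scores for the two classifiers, aligned
#'   subject-by-subject (equal length).
#' @param labels Case indicator for the same subjects: logical, 0/1, or a
#'   vector with values `"case"`/`"control"`.
#' @return An object of class `paired_auc_test`: `auc_a`, `auc_b`,
#'   `difference`, `var_diff`, `z`, `p_value`, `n_cases`, `n_controls`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must describe the same subjects")
  is_case <- as_case_indicator(labels)
  a_case <- scores_a[is_case]; a_ctrl <- scores_a[!is_case]
  b_case <- scores_b[is_case]; b_ctrl <- scores_b[!is_case]
  m <- sum(is_case); n <- sum(!is_case)
  if (m < 2L || n < 2L) stop("need at least 2 cases and 2 controls")
  auc_a <- empirical_auc(a_case, a_ctrl)
  auc_b <- empirical_auc(b_case, b_ctrl)
  pa <- placement_values(a_case, a_ctrl)
  pb <- placement_values(b_case, b_ctrl)
  var_a <- var(pa$cases) / m + var(pa$controls) / n
  var_b <- var(pb$cases) / m + var(pb$controls) / n
  cov_ab <- cov(pa$cases, pb$cases) / m + cov(pa$controls, pb$controls) / n
  vd <- max(0, var_a + var_b - 2 * cov_ab)
  d <- auc_a - auc_b
  z <- if (vd > 0) d / sqrt(vd) else if (d == 0) 0 else sign(d) * Inf
  structure(
    list(auc_a = auc_a, auc_b = auc_b, difference = d, var_diff = vd,
         z = z, p_value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)),
         n_cases = m, n_controls = n),
    class = "paired_auc_test")
}

#' Sensitivity at a fixed specificity
#'
#' Scans the empirical thresholds (positive when `score > t`) and returns the
#' maximum sensitivity among thresholds whose specificity is at least
#' `target_spec`.
#'
#' @param case_scores,control_scores Numeric score vectors, non-empty.
#' @param target_spec Required specificity (default 0.90).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(case_scores, control_scores,
                                       target_spec = 0.90) {
  stopifnot(length(case_scores) >= 1, length(control_scores) >= 1,
            target_spec >= 0, target_spec <= 1)
  thr <- sort(unique(c(case_scores, control_scores)))
  spec <- vapply(thr, function(t) mean(control_scores <= t), numeric(1))
  sens <- vapply(thr, function(t) mean(case_scores > t), numeric(1))
  ok <- spec >= target_spec
  if (!any(ok)) return(0)  # unreachable: the top threshold has specificity 1
  max(sens[ok])
}

#' Empirical ROC coordinates
#'
#' All distinct operating points of the empirical ROC curve under the
#' `score > threshold` positivity rule, for plotting.
#'
#' @inheritParams sensitivity_at_specificity
#' @return `data.frame` with `threshold`, `sensitivity`, `specificity`,
#'   ordered from the most permissive to the strictest threshold.
#' @export
roc_curve <- function(case_scores, control_scores) {
  thr <- c(-Inf, sort(unique(c(case_scores, control_scores))))
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(case_scores > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(control_scores <= t),
                         numeric(1)))
}

# normalize the various label encodings to a logical case indicator
as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("case", "control")))
    stop("labels must be logical, 0/1, or 'case'/'control'")
  lab == "case"
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "<roc_summary> AUC %.3f [%.3f-%.3f] (%d%% CI), p = %.4g (%s), %d cases / %d controls\n",
    x$auc, x$ci_low, x$ci_high, round(100 * x$level), x$p_value, x$p_method,
    x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
print.paired_auc_test <- function(x, ...) {
  cat(sprintf(
    "<paired_auc_test> AUC %.3f vs %.3f, diff %+.3f, z = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$difference, x$z, x$p_value))
  invisible(x)
}
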