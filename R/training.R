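# one stratified bootstrap draw: cases and controls resampled separately
# with replacement, preserving class counts; out-of-bag = subjects never drawn
stratified_bootstrap <- function(case_idx, ctrl_idx, n_total) {
  inbag <- c(sample(case_idx, length(case_idx), replace = TRUE),
             sample(ctrl_idx, length(ctrl_idx), replace = TRUE))
  list(inbag = inbag,
       oob = which(tabulate(inbag, nbins = n_total) == 0L))
}

#' Select the elasticnet penalty by stratified bootstrap out-of-bag AUC
#'
#' The model-selection procedure of the training stage: for each of `B`
#' bootstrap iterations, cases and controls are resampled separately with
#' replacement (preserving the class counts), the full penalty path is fitted
#' to the in-bag subjects, and the out-of-bag subjects are scored by every
#' path model; the penalty achieving the greatest mean out-of-bag AUC over
#' the `B` test sets is selected. Iterations whose out-of-bag set contains
#' fewer than two cases or two controls have no defined AUC and are skipped
#' and counted. Ties in the mean AUC resolve to the largest (sparsest)
#' penalty.
#'
#' Iteration-level seeds are drawn once from `seed`, so results do not depend
#' on execution order.
#'
#' @param fm A [feature_matrix()] of the training cohort.
#' @param alpha Lasso share of the penalty (default 0.95: 95% lasso,
#'   5% ridge).
#' @param B Number of bootstrap iterations (study default 10,000).
#' @param n_lambda,lambda_min_ratio Penalty grid, computed once from the full
#'   training data and reused for every in-bag fit.
#' @param seed Integer RNG seed.
#' @param kkt_tol Convergence tolerance for the in-bag fits; selection
#'   depends only on score ranks, so the default is looser than
#'   [fit_path()]'s.
#' @return Object of class `penalty_selection`: `lambdas`, `mean_oob_auc`,
#'   `n_valid` (iterations contributing per penalty), `oob_auc` (B x
#'   penalties matrix), `selected_lambda`, `selected_index`,
#'   `n_iterations`, `n_skipped`, `alpha`, `seed`.
#' @export
select_penalty <- function(fm, alpha = 0.95, B = 10000, n_lambda = 100,
                           lambda_min_ratio = 1e-3, seed = 1L,
                           kkt_tol = 1e-6) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (B < 1) stop("B must be at least 1")
  lambda <- lambda_grid(fm, alpha, n_lambda, lambda_min_ratio)
  x <- fm$x; y <- fm$y
  case_idx <- which(y == 1); ctrl_idx <- which(y == 0)
  m <- length(case_idx); n0 <- length(ctrl_idx)
  n <- length(y)

  with_seed(seed, {
    iter_seeds <- sample.int(.Machine$integer.max, B)
    oob_auc <- matrix(NA_real_, B, length(lambda))
    for (b in seq_len(B)) {
      set.seed(iter_seeds[b])
      bs <- stratified_bootstrap(case_idx, ctrl_idx, n)
      inbag <- bs$inbag; oob <- bs$oob
      if (sum(y[oob] == 1) < 2L || sum(y[oob] == 0) < 2L) next
      fit <- enet_path_cpp(x[inbag, , drop = FALSE], y[inbag], lambda,
                           alpha, kkt_tol = kkt_tol)
      scores <- x[oob, , drop = FALSE] %*% fit$beta
      scores <- sweep(scores, 2L, fit$intercept, `+`)
      oob_auc[b, ] <- auc_columns_cpp(scores, y[oob] == 1)
    }
    n_valid <- colSums(!is.na(oob_auc))
    if (any(n_valid == 0L))
      stop("no valid bootstrap iteration for some penalties; increase B")
    mean_auc <- colMeans(oob_auc, na.rm = TRUE)
    sel <- which(mean_auc == max(mean_auc))[1]  # grid decreasing: first = largest lambda
    structure(
      list(lambdas = lambda, mean_oob_auc = mean_auc, n_valid = n_valid,
           oob_auc = oob_auc, selected_lambda = lambda[sel],
           selected_index = sel, n_iterations = B,
           n_skipped = sum(rowSums(!is.na(oob_auc)) == 0L),
           alpha = alpha, seed = as.integer(seed)),
      class = "penalty_selection")
  })
}

#' Final fit at the selected penalty
#'
#' Refits the elasticnet-logistic model on the full training data at the
#' penalty chosen by [select_penalty()], warm-starting down a short path from
#' `lambda_max`. Markers with exactly-zero coefficients are excluded from the
#' panel.
#'
#' @param fm A [feature_matrix()] of the full training cohort.
#' @param selected_lambda Penalty from [select_penalty()] (or a
#'   `penalty_selection` object).
#' @param alpha Lasso share of the penalty.
#' @param kkt_tol Convergence tolerance on the exact KKT residual.
#' @return An `enet_model`.
#' @export
final_fit <- function(fm, selected_lambda, alpha = 0.95, kkt_tol = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (inherits(selected_lambda, "penalty_selection")) {
    alpha <- selected_lambda$alpha
    selected_lambda <- selected_lambda$selected_lambda
  }
  lmax <- lambda_grid(fm, alpha, n_lambda = 2, lambda_min_ratio = 0.5)[1]
  grid <- warm_grid(lmax, selected_lambda)
  path <- fit_path(fm, alpha = alpha, lambda = grid, kkt_tol = kkt_tol)
  path_model(path, selected_lambda)
}

# short decreasing grid from lmax to the target penalty (inclusive)
warm_grid <- function(lmax, target, length_out = 20) {
  if (target >= lmax) return(target)
  unique(c(exp(seq(log(lmax), log(target), length.out = length_out))[-length_out],
           target))
}

#' Bootstrap internal validation of training accuracy
#'
#' Estimates how well the selected model generalizes from the training data
#' alone. The default `"oob"` scheme refits the model at the selected penalty
#' on each stratified bootstrap sample and measures the AUC on the out-of-bag
#' subjects; the point estimate is the mean out-of-bag AUC and the interval
#' the 2.5/97.5 percentiles of the per-iteration AUCs. The `"optimism"`
#' alternative is Harrell-style: per iteration, optimism = (apparent AUC of
#' the bootstrap-refitted model on its own sample) - (its AUC on the full
#' data); the apparent full-data AUC minus the mean optimism is the corrected
#' estimate, with percentile bounds from the per-iteration corrected values.
#'
#' @param fm A [feature_matrix()] of the training cohort.
#' @param selected_lambda Penalty of the frozen model (or a
#'   `penalty_selection`).
#' @param alpha Lasso share of the penalty.
#' @param B Number of bootstrap iterations (>= 2; study default 10,000).
#' @param seed Integer RNG seed.
#' @param scheme `"oob"` (default) or `"optimism"`.
#' @param kkt_tol Convergence tolerance for the refits.
#' @return Object of class `bootstrap_validation`: `point_auc`, `ci_low`,
#'   `ci_high`, `n_iterations`, `n_skipped`, `scheme`, `seed`, and the
#'   per-iteration values as `iteration_auc`.
#' @export
bootstrap_validate <- function(fm, selected_lambda, alpha = 0.95, B = 10000,
                               seed = 1L, scheme = c("oob", "optimism"),
                               kkt_tol = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fm, "feature_matrix"))
  if (B < 2) stop("B must be at least 2")
  if (inherits(selected_lambda, "penalty_selection")) {
    alpha <- selected_lambda$alpha
    selected_lambda <- selected_lambda$selected_lambda
  }
  x <- fm$x; y <- fm$y
  case_idx <- which(y == 1); ctrl_idx <- which(y == 0)
  m <- length(case_idx); n0 <- length(ctrl_idx)
  n <- length(y)
  lmax_full <- lambda_grid(fm, alpha, n_lambda = 2, lambda_min_ratio = 0.5)[1]
  grid <- warm_grid(max(lmax_full, selected_lambda), selected_lambda)

  refit_scores <- function(idx, newx) {
    fit <- enet_path_cpp(x[idx, , drop = FALSE], y[idx], grid, alpha,
                         kkt_tol = kkt_tol)
    k <- length(grid)
    drop(newx %*% fit$beta[, k] + fit$intercept[k])
  }

  if (scheme == "optimism") {
    model <- final_fit(fm, selected_lambda, alpha, kkt_tol = 1e-8)
    apparent <- empirical_auc(
      drop(x[case_idx, , drop = FALSE] %*% model$beta) ,
      drop(x[ctrl_idx, , drop = FALSE] %*% model$beta))
  }

  with_seed(seed, {
    iter_seeds <- sample.int(.Machine$integer.max, B)
    vals <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      set.seed(iter_seeds[b])
      bs <- stratified_bootstrap(case_idx, ctrl_idx, n)
      inbag <- bs$inbag
      if (scheme == "oob") {
        oob <- bs$oob
        if (sum(y[oob] == 1) < 2L || sum(y[oob] == 0) < 2L) next
        s <- refit_scores(inbag, x[oob, , drop = FALSE])
        vals[b] <- empirical_auc(s[y[oob] == 1], s[y[oob] == 0])
      } else {
        s_in <- refit_scores(inbag, x[inbag, , drop = FALSE])
        s_all <- refit_scores(inbag, x)
        yin <- y[inbag]
        optimism <- empirical_auc(s_in[yin == 1], s_in[yin == 0]) -
          empirical_auc(s_all[y == 1], s_all[y == 0])
        vals[b] <- apparent - optimism
      }
    }
    ok <- vals[!is.na(vals)]
    if (length(ok) < 2L) stop("too few valid bootstrap iterations")
    ci <- unname(quantile(ok, c(0.025, 0.975), type = 7))
    point <- mean(ok)
    structure(
      list(point_auc = point,
           ci_low = min(ci[1], point), ci_high = max(ci[2], point),
           n_iterations = B, n_skipped = B - length(ok),
           iteration_auc = vals, scheme = scheme, seed = as.integer(seed)),
      class = "bootstrap_validation")
  })
}

#' @export
print.penalty_selection <- function(x, ...) {
  cat(sprintf(
    "<penalty_selection> %d bootstrap iterations (%d fully skipped); selected lambda = %.4g (mean OOB AUC %.3f) of %d grid points\n",
    x$n_iterations, x$n_skipped, x$selected_lambda,
    x$mean_oob_auc[x$selected_index], length(x$lambdas)))
  invisible(x)
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_validation> %s scheme: AUC %.3f [%.3f-%.3f], %d iterations (%d skipped)\n",
    x$scheme, x$point_auc, x$ci_low, x$ci_high, x$n_iterations, x$n_skipped))
  invisible(x)
}
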