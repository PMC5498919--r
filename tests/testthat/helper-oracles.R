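# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: exhaustive pair counting for the AUC,
# Newton-Raphson IRLS for unpenalized logistic fits, direct evaluation of the
# penalized objective, and brute-force grid search for tiny elasticnet
# problems.

# AUC by exhaustive comparison of every case-control pair, ties = 1/2
pair_count_auc <- function(cases, controls) {
  total <- 0
  for (a in cases)
    for (b in controls)
      total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# unpenalized logistic regression by damped Newton-Raphson on (b0, beta)
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  Xa <- cbind(1, X)
  th <- rep(0, ncol(Xa))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% th)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(Xa, p - y) / nrow(Xa)
    W <- p * (1 - p)
    H <- crossprod(Xa * W, Xa) / nrow(Xa)
    step <- solve(H, g)
    th <- th - step
    if (max(abs(step)) < tol) break
  }
  list(intercept = th[1], beta = th[-1])
}

# penalized logistic objective evaluated directly
enet_objective <- function(X, y, b0, beta, lambda, alpha) {
  eta <- drop(b0 + X %*% beta)
  mean(log1p(exp(eta)) - y * eta) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# brute-force minimizer for a single-feature lasso-logistic problem:
# coarse-to-fine grid search over (b0, beta)
brute_force_enet_1d <- function(x, y, lambda, alpha, span = 5, levels = 6) {
  ctr <- c(0, 0); width <- span
  for (l in seq_len(levels)) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    bts <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, beta = bts)
    obj <- mapply(function(b0, b) enet_objective(matrix(x), y, b0, b,
                                                 lambda, alpha),
                  grid$b0, grid$beta)
    ctr <- unlist(grid[which.min(obj), ])
    width <- width / 10
  }
  list(intercept = unname(ctr[1]), beta = unname(ctr[2]))
}

# small helper: feature matrix straight from a generated cohort
cohort_fm <- function(cohort, markers, ...) {
  feature_matrix(cohort[, markers, drop = FALSE], cohort$label, ...)
}

# marker specs with full control over the effect pattern
toy_specs <- function(deltas, kappa = 1, sigma = 0.5) {
  specs <- lapply(seq_along(deltas), function(i)
    marker_spec(paste0("M", i), mu_control = 1, sigma = sigma,
                delta_train = deltas[i], delta_valid = kappa * deltas[i]))
  names(specs) <- paste0("M", seq_along(deltas))
  specs
}
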