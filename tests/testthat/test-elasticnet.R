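set.seed(1)
toy_x <- matrix(exp(rnorm(60 * 3, sd = 0.7) + rep(c(0.6, 0, 0), each = 60)
                    * rep(rep(1:0, c(25, 35)), 3)), 60, 3,
                dimnames = list(NULL, c("A", "B", "C")))
toy_y <- rep(c("case", "control"), c(25, 35))

test_that("preprocessing is location invariant and retains its parameters", {
  fm1 <- feature_matrix(log(toy_x), toy_y, log_transform = FALSE)
  fm2 <- feature_matrix(log(toy_x) + 7, toy_y, log_transform = FALSE)
  expect_equal(fm1$x, fm2$x, tolerance = 1e-12)

  # two-subject toy {1, e}: log then standardize -> symmetric about 0
  fm3 <- feature_matrix(matrix(c(1, exp(1)), ncol = 1,
                               dimnames = list(NULL, "M")),
                        c("case", "control"))
  expect_equal(drop(fm3$x), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # identity mode passes values through untouched
  fm4 <- feature_matrix(toy_x, toy_y, log_transform = FALSE,
                        standardize = FALSE)
  expect_equal(unname(fm4$x), unname(toy_x))
  expect_equal(unname(fm4$preprocessing$scale), rep(1, 3))

  const <- cbind(toy_x, K = 1)
  expect_error(feature_matrix(const, toy_y), "zero-variance marker: K")
  neg <- toy_x; neg[1, 1] <- -2
  expect_error(feature_matrix(neg, toy_y), "positive")
  expect_error(feature_matrix(toy_x, rep("case", 60)), "both classes")
})

test_that("the fully penalized model is the intercept-only null fit", {
  fm <- feature_matrix(toy_x, toy_y)
  path <- fit_path(fm)
  expect_equal(path$beta[, 1], c(A = 0, B = 0, C = 0))
  expect_equal(path$intercepts[1], qlogis(mean(fm$y)), tolerance = 1e-9)
})

test_that("the weakly penalized solution matches an unpenalized Newton oracle", {
  fm <- feature_matrix(toy_x, toy_y)
  lam <- c(lambda_grid(fm, n_lambda = 30), 1e-9)
  path <- fit_path(fm, lambda = lam, kkt_tol = 1e-10)
  oracle <- newton_logistic(fm$x, fm$y)
  k <- length(lam)
  expect_lt(max(abs(path$beta[, k] - oracle$beta)), 1e-4)
  expect_lt(abs(path$intercepts[k] - oracle$intercept), 1e-4)
})

test_that("path solutions satisfy the KKT conditions and structural invariants", {
  fm <- feature_matrix(toy_x, toy_y)
  path <- fit_path(fm)
  expect_true(all(path$kkt < 1e-6))
  # sparsity non-increasing as lambda decreases
  nnz <- colSums(path$beta != 0)
  expect_true(all(diff(nnz) >= 0))
  # objective never worse than the null model at the same penalty
  null_b0 <- qlogis(mean(fm$y))
  for (i in seq_along(path$lambdas)) {
    obj <- enet_objective(fm$x, fm$y, path$intercepts[i], path$beta[, i],
                          path$lambdas[i], path$alpha)
    obj_null <- enet_objective(fm$x, fm$y, null_b0, rep(0, 3),
                               path$lambdas[i], path$alpha)
    expect_lte(obj, obj_null + 1e-12)
  }
})

test_that("single-feature lasso solution matches a brute-force grid oracle", {
  x <- c(-1.5, -0.5, 0.5, 1.5)
  y <- c(0, 1, 0, 1)  # overlapping classes: finite unpenalized optimum
  for (lam in c(0.02, 0.08, 0.3)) {
    fit <- lungpanel:::enet_path_cpp(matrix(x), y, lam, alpha = 1,
                                     kkt_tol = 1e-10)
    oracle <- brute_force_enet_1d(x, y, lam, alpha = 1)
    expect_equal(fit$beta[1, 1], oracle$beta, tolerance = 1e-3)
    expect_equal(fit$intercept[1], oracle$intercept, tolerance = 1e-3)
  }
})

test_that("coefficients agree with glmnet along a shared penalty grid", {
  skip_if_not_installed("glmnet")
  fm <- feature_matrix(toy_x, toy_y)
  lam <- lambda_grid(fm, n_lambda = 20, lambda_min_ratio = 0.01)
  path <- fit_path(fm, lambda = lam, kkt_tol = 1e-10)
  g <- glmnet::glmnet(fm$x, fm$y, family = "binomial", alpha = 0.95,
                      lambda = lam, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(as.matrix(g$beta) - path$beta)), 2e-3)
  expect_lt(max(abs(g$a0 - path$intercepts)), 2e-3)
})

test_that("scoring applies the frozen preprocessing and is rank-faithful", {
  fm <- feature_matrix(toy_x, toy_y)
  path <- fit_path(fm)
  model <- path_model(path, path$lambdas[60])
  s <- enet_score(model, toy_x)

  # logistic link does not change ranks
  expect_equal(
    empirical_auc(s[toy_y == "case"], s[toy_y == "control"]),
    empirical_auc(plogis(s)[toy_y == "case"], plogis(s)[toy_y == "control"]))

  null_model <- path_model(path, path$lambdas[1])
  expect_equal(unname(enet_score(null_model, toy_x)),
               rep(null_model$intercept, nrow(toy_x)))

  ident <- lungpanel:::new_enet_model(
    intercept = 2, beta = c(A = 1), lambda = 0, alpha = 1,
    preprocessing = list(log_transform = FALSE,
                         center = c(A = 0), scale = c(A = 1)))
  expect_equal(unname(enet_score(ident, toy_x[, "A", drop = FALSE])),
               unname(toy_x[, "A"]) + 2)
  expect_error(enet_score(model, toy_x[, 1:2]), "missing marker column")
})

test_that("models freeze to text and restore bit-for-bit", {
  fm <- feature_matrix(toy_x, toy_y)
  model <- final_fit(fm, lambda_grid(fm)[40])
  f <- tempfile(fileext = ".txt")
  write_model(model, f)
  back <- read_model(f)
  expect_identical(back$beta, model$beta)
  expect_identical(back$intercept, model$intercept)
  expect_identical(back$lambda, model$lambda)
  expect_identical(enet_score(back, toy_x), enet_score(model, toy_x))
  expect_match(model_checksum(f), "^[0-9a-f]{32}$")
  unlink(f)
})
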