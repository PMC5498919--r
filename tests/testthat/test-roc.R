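test_that("empirical AUC equals exhaustive pair counting, including ties", {
  expect_equal(empirical_auc(c(3, 5, 7), c(2, 4, 6)), 6 / 9)
  expect_equal(empirical_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(empirical_auc(rep(2, 4), rep(2, 3)), 0.5)
  set.seed(101)
  for (i in 1:300) {
    m <- sample(1:12, 1); n <- sample(1:12, 1)
    cases <- sample(0:6, m, replace = TRUE) + sample(c(0, 0.5), m, TRUE)
    ctrls <- sample(0:6, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    expect_identical(empirical_auc(cases, ctrls), pair_count_auc(cases, ctrls))
  }
})

test_that("AUC complementarity and rank invariance hold", {
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(15); b <- rnorm(20)
    expect_equal(empirical_auc(a, b) + empirical_auc(b, a), 1)
    tr <- function(x) exp(2 * x) + 3   # strictly increasing
    expect_equal(empirical_auc(tr(a), tr(b)), empirical_auc(a, b))
  }
})

test_that("DeLong summary agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:12) {
    m <- sample(10:40, 1); n <- sample(10:40, 1)
    cases <- round(rnorm(m, 1), i %% 3)  # some iterations induce ties
    ctrls <- round(rnorm(n, 0), i %% 3)
    s <- delong_summary(cases, ctrls)
    r <- pROC::roc(controls = ctrls, cases = cases, quiet = TRUE,
                   direction = "<")
    expect_equal(s$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    expect_equal(s$var_auc, pROC::var(r, method = "delong"),
                 tolerance = 1e-9)
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
    expect_equal(c(s$ci_low, s$ci_high), pmin(1, pmax(0, ci[c(1, 3)])),
                 tolerance = 1e-9)
  }
})

test_that("DeLong summary AUC is exactly the empirical AUC and CIs behave", {
  set.seed(13)
  cases <- rnorm(30, 1); ctrls <- rnorm(25)
  s <- delong_summary(cases, ctrls)
  expect_identical(s$auc, empirical_auc(cases, ctrls))
  expect_true(s$ci_low <= s$auc && s$auc <= s$ci_high)
  # perfect separation: zero variance, degenerate CI at 1
  sp <- delong_summary(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sp$var_auc, 0)
  expect_equal(c(sp$ci_low, sp$ci_high), c(1, 1))
  expect_lt(sp$p_value, 1e-10)
})

test_that("paired DeLong test handles identity, rank invariance, and matches pROC", {
  set.seed(17)
  y <- rep(c(1, 0), c(20, 25))
  a <- rnorm(45) + y
  same <- delong_paired_test(a, a, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(a, exp(a) + 2, y)
  expect_equal(mono$difference, 0)

  skip_if_not_installed("pROC")
  for (i in 1:8) {
    b <- rnorm(45) + 0.5 * y
    t1 <- delong_paired_test(a, b, y)
    ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
    rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
    t2 <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(t1$p_value, t2$p.value, tolerance = 1e-9)
    expect_equal(t1$difference, as.numeric(t2$estimate[1] - t2$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("paired-test variance is consistent with a paired bootstrap", {
  set.seed(23)
  y <- rep(c(1, 0), each = 30)
  a <- rnorm(60) + y
  b <- 0.6 * a + 0.8 * rnorm(60) + 0.4 * y
  t1 <- delong_paired_test(a, b, y)
  boots <- replicate(4000, {
    ic <- sample(which(y == 1), replace = TRUE)
    ik <- sample(which(y == 0), replace = TRUE)
    idx <- c(ic, ik)
    empirical_auc(a[idx][y[idx] == 1], a[idx][y[idx] == 0]) -
      empirical_auc(b[idx][y[idx] == 1], b[idx][y[idx] == 0])
  })
  expect_equal(t1$var_diff, var(boots), tolerance = 0.35)
})

test_that("sensitivity at fixed specificity matches a brute-force threshold scan", {
  brute <- function(cases, ctrls, target) {
    thr <- sort(unique(c(cases, ctrls)))
    best <- 0
    for (t in thr) {
      spec <- mean(ctrls <= t)
      if (spec >= target) best <- max(best, mean(cases > t))
    }
    best
  }
  expect_equal(sensitivity_at_specificity(1:10, 1:10, 0.90), 0.10)
  expect_equal(sensitivity_at_specificity(c(5, 6, 7), c(1, 2, 3), 0.99), 1)
  set.seed(29)
  for (i in 1:40) {
    cases <- sample(1:15, 12, replace = TRUE)
    ctrls <- sample(1:15, 10, replace = TRUE)
    tg <- runif(1)
    expect_equal(sensitivity_at_specificity(cases, ctrls, tg),
                 brute(cases, ctrls, tg))
  }
  # monotone in the target
  cases <- rnorm(30, 1); ctrls <- rnorm(30)
  sens <- vapply(seq(0.5, 1, by = 0.05), function(t)
    sensitivity_at_specificity(cases, ctrls, t), numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("degenerate ROC inputs are rejected", {
  expect_error(empirical_auc(numeric(0), 1:3), "non-empty")
  expect_error(delong_summary(1, c(1, 2)), "at least 2")
  expect_error(delong_paired_test(1:4, 1:5, rep(0:1, 2)), "same subjects")
})
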