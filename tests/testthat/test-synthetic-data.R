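test_that("validation cohorts reproduce the configured structure exactly", {
  specs <- default_marker_specs()
  co <- generate_cohort(validation_config("nodule", seed = 42), specs)

  expect_equal(nrow(co), 238)
  expect_equal(sum(co$label == "case"), 119)
  expect_true(all(co$finding == "nodule"))

  cases <- co[co$label == "case", ]
  expect_equal(sum(cases$stage == "IA", na.rm = TRUE), 51)
  expect_equal(sum(cases$stage == "IB", na.rm = TRUE), 15)
  expect_equal(sum(cases$stage == "II", na.rm = TRUE), 10)
  expect_equal(sum(cases$stage == "III", na.rm = TRUE), 19)
  expect_equal(sum(cases$stage == "IV", na.rm = TRUE), 14)
  expect_equal(sum(is.na(cases$stage)), 5)
  expect_equal(sum(cases$histology == "Adenocarcinoma"), 57)
  expect_equal(sum(cases$histology == "Squamous cell"), 25)

  ctrl <- co[co$label == "control", ]
  expect_true(all(is.na(ctrl$stage)) && all(is.na(ctrl$histology)))
  expect_true(all(as.matrix(co[, names(specs)]) > 0))
})

test_that("validation pairs are individually matched within the caliper", {
  co <- generate_cohort(validation_config("mass", seed = 3),
                        default_marker_specs())
  cases <- co[co$label == "case", ]
  ctrl <- co[co$label == "control", ]
  expect_equal(sort(cases$match_id), sort(ctrl$match_id))
  expect_equal(anyDuplicated(cases$match_id), 0)
  ctrl <- ctrl[match(cases$match_id, ctrl$match_id), ]
  expect_identical(cases$finding, ctrl$finding)
  expect_identical(cases$gender, ctrl$gender)
  expect_true(all(abs(cases$age - ctrl$age) <= 5))
  expect_true(all(abs(cases$pack_years - ctrl$pack_years) <= 20))
})

test_that("training cohort matches the study sizes and is reproducible", {
  specs <- default_marker_specs()
  co <- generate_cohort(training_config(seed = 9), specs)
  expect_equal(sum(co$label == "case"), 95)
  expect_equal(sum(co$label == "control"), 186)
  expect_true(all(is.na(co$finding)))
  expect_true(all(is.na(co$match_id)))
  co2 <- generate_cohort(training_config(seed = 9), specs)
  expect_identical(co, co2)
})

test_that("null markers score at chance and informative markers follow the closed form", {
  # delta = 0: AUC ~ 0.5 within Monte-Carlo error
  specs0 <- toy_specs(c(0, 0, 0))
  cfg <- cohort_config(200, 200, "training", seed = 5)
  co <- generate_cohort(cfg, specs0)
  for (mk in names(specs0)) {
    auc <- empirical_auc(co[[mk]][co$label == "case"],
                         co[[mk]][co$label == "control"])
    expect_lt(abs(auc - 0.5), 0.08)
  }
  # delta = 3: limit AUC = pnorm(3 / sqrt(2)) ~ 0.983; demand > 0.95
  specs3 <- toy_specs(3)
  co3 <- generate_cohort(cohort_config(200, 200, "training", seed = 6), specs3)
  auc3 <- empirical_auc(co3$M1[co3$label == "case"],
                        co3$M1[co3$label == "control"])
  expect_gt(auc3, 0.95)
  expect_lt(abs(auc3 - pnorm(3 / sqrt(2))), 0.03)
})

test_that("null case and control log-levels are distributionally indistinguishable", {
  specs <- toy_specs(0)
  reject <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_config(100, 100, "training", seed = s), specs)
    p <- suppressWarnings(
      stats::ks.test(log(co$M1[co$label == "case"]),
                     log(co$M1[co$label == "control"]))$p.value)
    p < 0.01
  }, logical(1))
  expect_lte(sum(reject), 2)  # >= 95% of seeds fail to reject at alpha = 0.01
})

test_that("attenuation kappa delivers the requested single-marker AUC drop", {
  k <- attenuation_kappa(0.8, drop = 0.10)
  expect_lt(k, 1)
  expect_equal(pnorm(0.8 / sqrt(2)) - pnorm(k * 0.8 / sqrt(2)), 0.10,
               tolerance = 1e-12)
  # population AUCs of the generator follow the configured shifts
  specs <- toy_specs(0.8, kappa = k)
  co <- generate_cohort(cohort_config(3000, 3000, "validation", seed = 8), specs)
  auc <- empirical_auc(co$M1[co$label == "case"],
                       co$M1[co$label == "control"])
  expect_equal(auc, pnorm(k * 0.8 / sqrt(2)), tolerance = 0.03)
})

test_that("clotting series has the stated shape and deterministic drift", {
  specs <- default_marker_specs()
  ser <- generate_clotting_series(specs, n_donors = 6, noise_sd = 0.05,
                                  seed = 2)
  expect_equal(nrow(ser), 6 * 3 * length(specs))
  expect_equal(sum(ser$marker == "MDK"), 18)
  expect_setequal(unique(ser$time_h), c(0.5, 4, 24))

  # zero noise: later timepoints are exact multiples of the baseline
  one <- toy_specs(0)
  one$M1$drift_4h <- 0.74; one$M1$drift_24h <- 0.52
  s0 <- generate_clotting_series(one, n_donors = 4, noise_sd = 0, seed = 3)
  base <- s0$level[s0$time_h == 0.5]
  expect_equal(s0$level[s0$time_h == 4], base * 0.74, tolerance = 1e-12)
  expect_equal(s0$level[s0$time_h == 24], base * 0.52, tolerance = 1e-12)

  flat <- toy_specs(0)  # drift 1 by default
  sf <- generate_clotting_series(flat, n_donors = 3, noise_sd = 0, seed = 4)
  expect_equal(sf$level[sf$time_h == 4], sf$level[sf$time_h == 0.5])
  expect_equal(sf$level[sf$time_h == 24], sf$level[sf$time_h == 0.5])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(10, 12, "validation"), "1:1 matched")
  expect_error(cohort_config(10, 10, "training",
                             stage_mix = c(IA = 0.5, IB = 0.4)),
               "sum to 1")
  expect_error(cohort_config(10, 10, "training", correlation = 1),
               "correlation")
  expect_error(generate_cohort(cohort_config(5, 5, "training"), list()),
               "at least one")
})
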