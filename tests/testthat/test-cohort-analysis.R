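specs <- default_marker_specs()
nodule_cohort <- generate_cohort(validation_config("nodule", seed = 19), specs)

make_model <- function(beta) {
  mk <- names(beta)
  lungpanel:::new_enet_model(
    intercept = 0, beta = beta, lambda = 0.01, alpha = 0.95,
    preprocessing = list(log_transform = TRUE,
                         center = setNames(rep(0, length(mk)), mk),
                         scale = setNames(rep(1, length(mk)), mk)))
}

test_that("a single-marker panel scores identically to the raw marker", {
  model <- make_model(c(CEA = 1.3))
  rep <- validate_cohort(model, nodule_cohort, subgroups = list())
  panel <- rep$analyses[rep$analyses$analysis == "PNC (nodule)", ]
  cea <- rep$analyses[rep$analyses$analysis == "CEA (nodule)", ]
  expect_equal(panel$auc, cea$auc)
  expect_equal(panel$p_value, cea$p_value)
})

test_that("canonical subgroups reproduce the configured stratum sizes", {
  defs <- canonical_subgroups(nodule_cohort)
  nm <- vapply(defs, `[[`, character(1), "name")
  expect_true(all(c("stage IA (nodule)", "adenocarcinoma (nodule)",
                    "squamous cell (nodule)", "other histology (nodule)",
                    "finding: nodule") %in% nm))
  model <- make_model(c(CEA = 1, CYFRA21_1 = 0.5))
  rep <- validate_cohort(model, nodule_cohort)
  an <- rep$analyses
  row <- function(x) an[an$analysis == x, ]
  expect_equal(row("stage IA (nodule)")[, c("n_cases", "n_controls")],
               data.frame(n_cases = 51, n_controls = 119),
               ignore_attr = TRUE)
  expect_equal(row("stage IB (nodule)")$n_cases, 15)
  expect_equal(row("stage IV (nodule)")$n_cases, 14)
  expect_equal(row("adenocarcinoma (nodule)")$n_cases, 57)
  expect_equal(row("squamous cell (nodule)")$n_cases, 25)
  expect_equal(row("other histology (nodule)")$n_cases, 37)
  # stage subgroup cases partition the substaged cases
  staged <- nodule_cohort$label == "case" &
    nodule_cohort$stage %in% c("IA", "IB", "II", "III", "IV")
  stage_rows <- an[grepl("^stage ", an$analysis), ]
  expect_equal(sum(stage_rows$n_cases), sum(staged))
  expect_identical(canonical_subgroups(nodule_cohort[0, ]), list())
})

test_that("finding strata never share controls and training cohorts fall back to one stratum", {
  co <- rbind(generate_cohort(validation_config("nodule", seed = 4), specs),
              generate_cohort(validation_config("mass", seed = 5), specs))
  co$subject_id <- sprintf("s%04d", seq_len(nrow(co)))
  model <- make_model(c(CEA = 1))
  rep <- validate_cohort(model, co)
  an <- rep$analyses
  expect_equal(an[an$analysis == "finding: mass", "n_controls"], 50)
  expect_equal(an[an$analysis == "finding: nodule", "n_controls"], 119)
  expect_equal(an[an$analysis == "PNC (mass)", "n_cases"], 50)

  tr <- generate_cohort(training_config(seed = 6), specs)
  rep_tr <- validate_cohort(model, tr, subgroups = list())
  expect_equal(rep_tr$analyses[1, "analysis"], "PNC (all)")
  expect_equal(rep_tr$analyses[1, "n_controls"], 186)
})

test_that("validation never mutates the frozen model and records its hash", {
  model <- make_model(c(CEA = 1, OPN = -0.2))
  before <- unserialize(serialize(model, NULL))
  f <- tempfile(); write_model(model, f)
  rep <- validate_cohort(model, nodule_cohort, model_path = f)
  expect_identical(model, before)
  expect_identical(rep$model_hash, model_checksum(f))
  unlink(f)
})

test_that("undersized subgroups are flagged, not computed", {
  defs <- list(subgroup_definition("stage IV (mass)", case_stage = "IV",
                                   case_finding = "mass",
                                   control_finding = "mass"))
  model <- make_model(c(CEA = 1))
  rep <- validate_cohort(model, nodule_cohort, subgroups = defs)
  row <- rep$analyses[rep$analyses$analysis == "stage IV (mass)", ]
  expect_true(row$flagged)
  expect_true(is.na(row$auc))
})

test_that("AUC delta table measures attenuation and validates its inputs", {
  tr <- c(CEA = 0.71, OPN = 0.70)
  expect_equal(auc_delta_table(tr, tr)$delta, c(0, 0))
  va <- c(OPN = 0.62, CEA = 0.60)  # order-insensitive join
  d <- auc_delta_table(tr, va)
  expect_equal(d$delta, c(0.11, 0.08))
  expect_equal(attr(d, "mean_delta"), 0.095)
  expect_error(auc_delta_table(tr, c(CEA = 0.6, SCC = 0.5)), "SCC")

  # kappa = 1: no attenuation, deltas vanish up to Monte-Carlo error
  sp <- toy_specs(rep(0.8, 5), kappa = 1)
  tr_co <- generate_cohort(cohort_config(150, 150, "training", seed = 31), sp)
  va_co <- generate_cohort(cohort_config(150, 150, "validation", seed = 32), sp)
  mk_auc <- function(co) vapply(names(sp), function(m)
    empirical_auc(co[[m]][co$label == "case"], co[[m]][co$label == "control"]),
    numeric(1))
  d0 <- auc_delta_table(mk_auc(tr_co), mk_auc(va_co))
  expect_lt(abs(attr(d0, "mean_delta")), 0.06)
})
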