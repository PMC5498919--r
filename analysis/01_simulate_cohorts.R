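#!/usr/bin/env Rscript

# Stage 1 of the workflow: materialize the synthetic study data.
#
# Emulates the three data sets of the study design: a clotting-time series
# from 6 healthy donors (9 candidate markers at 0.5/4/24 h), a training
# cohort of 95 early-stage NSCLC cases vs 186 smoker controls, and a blinded
# validation cohort of individually matched case-control pairs per
# radiographic finding stratum (119 nodule, 50 mass, 28 other pairs).
# Cases carry attenuated marker shifts in the validation scenario.

suppressPackageStartupMessages(library(lungpanel))

seed <- as.integer(Sys.getenv("LP_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- default_marker_specs()
message(sprintf("markers: %s", paste(names(specs), collapse = ", ")))
message(sprintf("informative training shift delta = %.2f, attenuation kappa = %.3f",
                specs$CEA$delta_train, specs$CEA$delta_valid / specs$CEA$delta_train))

series <- generate_clotting_series(specs, n_donors = 6, noise_sd = 0.05,
                                   seed = seed)
write_clotting_series(series, file.path(out, "clotting_series.csv"))
message(sprintf("clotting series: %d donors x 3 timepoints x %d markers -> %d rows",
                6, length(specs), nrow(series)))

train <- generate_cohort(training_config(seed = seed + 1L), specs)
write_cohort(train, file.path(out, "training_cohort.csv"))
message(sprintf("training cohort: %d cases / %d controls",
                sum(train$label == "case"), sum(train$label == "control")))

valid <- do.call(rbind, lapply(c("nodule", "mass", "other"), function(fd) {
  i <- match(fd, c("nodule", "mass", "other"))
  co <- generate_cohort(validation_config(fd, seed = seed + 3L + i), specs)
  co$match_id <- paste0(fd, "_", co$match_id)
  co
}))
valid$subject_id <- sprintf("v_%04d", seq_len(nrow(valid)))
write_cohort(valid, file.path(out, "validation_cohort.csv"))
message(sprintf("validation cohort: %d matched pairs (%s)",
                sum(valid$label == "case"),
                paste(sprintf("%s %d", c("nodule", "mass", "other"),
                              c(119, 50, 28)), collapse = ", ")))
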