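#!/usr/bin/env Rscript

# Stage 3: panel training.
#
# Elasticnet-penalized logistic regression (95% lasso / 5% ridge) of lung
# cancer status on the log-standardized retained markers. The penalty is
# chosen by stratified bootstrap resampling: each iteration refits the full
# penalty path on an in-bag resample (class counts preserved) and scores the
# out-of-bag subjects; the penalty with the greatest mean OOB AUC wins. The
# final model is refitted to the full cohort at that penalty, frozen to
# disk, and internally validated by a second bootstrap.
#
# B defaults to 2,000 here to keep the driver quick; the study value is
# 10,000 (LP_B=10000 reproduces it).

suppressPackageStartupMessages(library(lungpanel))

seed <- as.integer(Sys.getenv("LP_SEED", "1"))
B <- as.integer(Sys.getenv("LP_B", "2000"))
out <- "results/training"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

train <- read_cohort("results/data/training_cohort.csv")
retained <- readLines("results/stability/retained_markers.txt")
message(sprintf("training on %d subjects x %d retained markers, B = %d",
                nrow(train), length(retained), B))

fm <- feature_matrix(train[, retained], train$label)
sel <- select_penalty(fm, alpha = 0.95, B = B, seed = seed + 10L)
print(sel)
write.csv(data.frame(lambda = sel$lambdas, mean_oob_auc = sel$mean_oob_auc,
                     n_valid = sel$n_valid),
          file.path(out, "selection_curve.csv"), row.names = FALSE)

model <- final_fit(fm, sel)
print(model)
write_model(model, file.path(out, "model.txt"))
message(sprintf("frozen model md5: %s",
                model_checksum(file.path(out, "model.txt"))))

score <- enet_score(model, train)
apparent <- delong_summary(score[train$label == "case"],
                           score[train$label == "control"])
message(sprintf("apparent training AUC %.3f [%.3f-%.3f], p = %.2g",
                apparent$auc, apparent$ci_low, apparent$ci_high,
                apparent$p_value))

boot <- bootstrap_validate(fm, sel, B = B, seed = seed + 11L)
message(sprintf("bootstrap-validated AUC %.3f [%.3f-%.3f] (%d iterations)",
                boot$point_auc, boot$ci_low, boot$ci_high, boot$n_iterations))

write.csv(data.frame(
  quantity = c("apparent_auc", "apparent_ci_low", "apparent_ci_high",
               "bootstrap_auc", "bootstrap_ci_low", "bootstrap_ci_high",
               "selected_lambda", "panel_size"),
  value = c(apparent$auc, apparent$ci_low, apparent$ci_high, boot$point_auc,
            boot$ci_low, boot$ci_high, sel$selected_lambda,
            length(panel_markers(model)))),
  file.path(out, "training_report.csv"), row.names = FALSE)
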