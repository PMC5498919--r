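#!/usr/bin/env Rscript

# Stage 4: blinded validation.
#
# Applies the frozen classifier unchanged to the independent matched
# case-control cohort and produces the validation result set: panel and
# single-marker DeLong ROC summaries per finding stratum, tumor-stage and
# histology subgroup AUCs (nodule cases vs the full benign-nodule control
# group), sensitivity at 90% specificity, per-marker train-vs-validation
# AUC deltas, and panel-score distribution summaries.

suppressPackageStartupMessages(library(lungpanel))

out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model_path <- "results/training/model.txt"
model <- read_model(model_path)
cohort <- read_cohort("results/data/validation_cohort.csv")
train <- read_cohort("results/data/training_cohort.csv")
message(sprintf("scoring %d subjects with frozen model (md5 %s)",
                nrow(cohort), substr(model_checksum(model_path), 1, 8)))

report <- validate_cohort(model, cohort, model_path = model_path)
print(report)
write.csv(report$analyses, file.path(out, "validation_report.csv"),
          row.names = FALSE)
write.csv(report$score_summary, file.path(out, "score_summary.csv"),
          row.names = FALSE)

nodule <- cohort[cohort$finding == "nodule", ]
s <- enet_score(model, nodule)
sens <- sensitivity_at_specificity(s[nodule$label == "case"],
                                   s[nodule$label == "control"], 0.90)
message(sprintf("sensitivity at 90%% specificity (nodule stratum): %.1f%%",
                100 * sens))
write.csv(roc_curve(s[nodule$label == "case"], s[nodule$label == "control"]),
          file.path(out, "roc_nodule_panel.csv"), row.names = FALSE)

# attenuation of the panel markers between studies
mk_auc <- function(co, mk) empirical_auc(co[[mk]][co$label == "case"],
                                         co[[mk]][co$label == "control"])
panel <- panel_markers(model)
deltas <- auc_delta_table(
  setNames(vapply(panel, mk_auc, numeric(1), co = train), panel),
  setNames(vapply(panel, mk_auc, numeric(1), co = nodule), panel))
print(deltas)
message(sprintf("mean panel-marker AUC fall (train -> validation): %.3f",
                attr(deltas, "mean_delta")))
write.csv(deltas, file.path(out, "auc_delta_table.csv"), row.names = FALSE)

# paired DeLong comparison: panel vs its strongest single marker
strongest <- panel[which.max(abs(model$beta[panel]))]
cmp <- delong_paired_test(enet_score(model, nodule), nodule[[strongest]],
                          nodule$label)
message(sprintf("panel vs %s (paired DeLong): dAUC %+.3f, p = %.3f",
                strongest, cmp$difference, cmp$p_value))
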