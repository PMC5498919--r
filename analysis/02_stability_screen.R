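#!/usr/bin/env Rscript

# Stage 2: pre-analytical stability screen.
#
# Quantifies, per candidate marker, the relative change of serum levels
# after 4 h and 24 h of clotting against the 0.5 h baseline, and deselects
# markers whose mean change exceeds 20% at either timepoint before any
# model sees the data.

suppressPackageStartupMessages(library(lungpanel))

series <- read_clotting_series("results/data/clotting_series.csv")
out <- "results/stability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

report <- relative_change(series)
print(report)

retained <- deselect_markers(report, threshold = 0.20)
write.csv(as.data.frame(report), file.path(out, "stability_report.csv"),
          row.names = FALSE)
writeLines(retained, file.path(out, "retained_markers.txt"))

dropped <- attr(retained, "deselected")
message(sprintf("deselected (|mean change| > 20%%): %s",
                if (length(dropped)) paste(dropped, collapse = ", ") else "none"))
message(sprintf("%d markers enter panel training: %s",
                length(retained), paste(retained, collapse = ", ")))
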