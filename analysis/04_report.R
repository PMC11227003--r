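#!/usr/bin/env Rscript
# Produce the tabular data behind the summary displays: the per-patient
# agitation proportion by clock block (the sundowning gradient), the median
# standardized-feature differences of motor-/verbal-agitated surveys
# against the non-agitated reference, and the same differences per patient
# on the consistent-availability five-patient subset.  These summaries are
# descriptive by design: no significance tests and no confounder
# adjustment.
#
# Reads results/surveys_clean.csv and results/model_rows.csv; writes
# results/proportions_by_block.csv, results/median_diff_by_type.csv,
# results/median_diff_by_patient.csv.

library(agitsense)

sv <- read.csv("results/surveys_clean.csv")
rows <- read.csv("results/model_rows.csv")

pr <- proportion_by_time_group(sv)
write.csv(pr, "results/proportions_by_block.csv", row.names = FALSE)
pooled <- tapply(pr$n_agitated, pr$time_group, sum) /
  tapply(pr$n_surveys, pr$time_group, sum)
cat("Pooled agitation proportion by clock block (8-12 / 12-16 / 16-20 / 20-8):\n")
print(round(pooled, 3))

by_type <- median_difference_table(rows, "agitation_type")
write.csv(by_type, "results/median_diff_by_type.csv", row.names = FALSE)

subset5 <- select_visualization_subset(
  rows[!duplicated(paste(rows$survey_id, rows$modality)), ])
cat("\nConsistent-availability subset:", paste(subset5, collapse = ", "), "\n")
by_patient <- median_difference_table(rows, "patient", patients = subset5)
write.csv(by_patient, "results/median_diff_by_patient.csv", row.names = FALSE)

up <- by_type[by_type$difference > 0 & !by_type$small_group, ]
cat(sprintf("\n%d of %d (feature, group) medians lie above the non-agitated reference;\n",
            nrow(up), sum(!by_type$small_group)))
cat("electrodermal features shifted up in both motor and verbal groups:\n")
eda_up <- up[grepl("^eda", up$signal), ]
print(head(eda_up[c("group", "signal", "feature", "difference")], 12),
      row.names = FALSE, digits = 2)
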