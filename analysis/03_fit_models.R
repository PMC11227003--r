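#!/usr/bin/env Rscript
# Fit the per-feature logistic mixed models: for every (signal, feature)
# and each outcome (overall / motor / verbal agitation), one model with the
# standardized feature, the clock block (time_group, reference 8-12 h), and
# the modality-specific confounder (mean ambient temperature for
# electrodermal and skin-temperature features, acceleration-magnitude SD
# for heart-rate features) as fixed effects plus a patient random
# intercept.  P-values are Wald, unadjusted.
#
# Reads results/model_rows.csv; writes results/coefficients.csv.

library(agitsense)

rows <- read.csv("results/model_rows.csv")
screen <- run_feature_screen(rows)
tab <- coefficient_table(screen)
write.csv(tab, "results/coefficients.csv", row.names = FALSE)

cat(sprintf("Fitted %d models (%d converged)\n", nrow(tab), sum(tab$converged)))
sig <- tab[!is.na(tab$p) & tab$p < 0.05, ]
cat(sprintf("%d significant at p < .05 (no multiplicity correction)\n", nrow(sig)))
cat("\nSignature features, overall agitation:\n")
show <- tab[tab$outcome == "agitated" &
              paste(tab$signal, tab$feature) %in%
              c("eda_tonic sd", "eda_tonic max", "eda_phasic median",
                "hr median", "st median", "acc_magnitude sd"), ]
print(show[c("signal", "feature", "estimate", "se", "p", "stars")],
      row.names = FALSE, digits = 3)
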