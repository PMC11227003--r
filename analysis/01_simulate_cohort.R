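#!/usr/bin/env Rscript
# Simulate the synthetic ward cohort that stands in for the (private)
# clinical data set: 30 patients, ~1 week each, nine pseudorandom survey
# prompts per day plus spontaneous surveys, and ground-truth agitation
# episodes that perturb the wearable physiology.
#
# Writes results/cohort/: surveys, episode ground truth, a config manifest,
# and -- as a format illustration -- full wear-day sensor streams for the
# first patient-day.

library(agitsense)

cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort, "results/cohort", patients = 1, days = 1)

cat(sprintf("Cohort: %d patients x %d days, %d surveys (%d prompted, %d spontaneous), %d episodes\n",
            cfg$n_patients, cfg$days_per_patient, nrow(cohort$surveys),
            sum(cohort$surveys$prompted), sum(!cohort$surveys$prompted),
            nrow(cohort$episodes)))
cat(sprintf("Episode types: %s\n",
            paste(names(table(cohort$episodes$type)),
                  table(cohort$episodes$type), collapse = ", ")))
cat("Files written under results/cohort/\n")
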