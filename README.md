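# agitsense

Momentary analysis of wrist-wearable physiology during agitation in
dementia.

## The problem

Agitation — excessive motor activity, verbal or physical aggression driven
by emotional distress — affects most people with dementia at some point and
is largely invisible between nursing observations.  If autonomic arousal
leaves a signature in wrist-worn sensor data *at the moment* agitation is
observed, those signals can become digital biomarkers for detection.
`agitsense` implements the full analysis chain for that question, aimed at
biostatisticians and digital-biomarker researchers working with
experience-sampling ward studies:

* observer surveys (PAS item scores, RASS) prompted nine times per day at
  pseudorandom times between 08:45 and 20:45 (minimum 50-minute spread),
  plus spontaneous surveys; duplicates within 5 minutes removed;
* a 6-minute window centered on each survey, cut from tri-axial
  acceleration (32 Hz), heart rate (0.5 Hz with missing markers),
  electrodermal activity (EDA, 256 or 8 Hz), skin temperature (1 Hz), and
  ward ambient temperature;
* per-modality quality control: rolling-median + cubic-spline heart-rate
  imputation with a 50 % missingness drop rule, a 20–40 °C skin-temperature
  validity rule, Savitzky–Golay filtering and a rule-based quality
  indicator (0.5 keep/drop threshold) with artifact interpolation for EDA;
* EDA deconvolution into tonic (SCL) and phasic (SCR) components using a
  Bateman impulse response and nonnegative ridge least squares;
* minimal interpretable features per window (min, max, median, SD; slope
  for skin temperature), z-scored within patient;
* one logistic generalized linear mixed model per feature and outcome
  (overall / motor / verbal agitation):

  logit P(agitated_ij = 1) = beta0 + beta1 z_ij + time_group_ij
                              + confounder_ij + u_i,   u_i ~ N(0, sigma_u^2)

  with `time_group` the clock block (8–12 / 12–16 / 16–20 / 20–8,
  reference 8–12), ambient temperature as confounder for EDA/ST models and
  acceleration SD for HR models, Wald tests, no multiplicity correction.
  The marginal likelihood uses a sixth-order-corrected Laplace
  approximation, verified against an adaptive Gauss–Hermite oracle.

The clinical recordings such studies produce are private, so the package
includes a fully synthetic ward-cohort generator (30 patients × 7 days by
default) that reproduces the design — prompt schedules, sundowning (an
agitation hazard rising across the day), nonwear and sensor missingness —
and plants a known autonomic signature (EDA and heart rate up, distal skin
temperature down, movement variability up in motor agitation).  Every
pipeline stage is validated against that ground truth.

## Worked example

```r
library(agitsense)

cfg  <- sim_config(n_patients = 6, days_per_patient = 3, seed = 42)
pipe <- run_pipeline(cfg)   # simulate, window, QC, decompose, standardize

cat(sprintf("%d surveys, %.1f%% agitated\n",
            nrow(pipe$surveys), 100 * mean(pipe$surveys$agitated)))
pr <- proportion_by_time_group(pipe$surveys)
pooled <- tapply(pr$n_agitated, pr$time_group, sum) /
          tapply(pr$n_surveys, pr$time_group, sum)
print(round(pooled, 2))

sub <- subset(pipe$model_rows, signal == "eda_tonic" & feature == "max")
coefficient_table(run_feature_screen(sub, outcomes = "agitated"))
```

Output:

```
177 surveys, 18.6% agitated
   1    2    3    4
0.15 0.09 0.25 0.39
     signal feature  outcome estimate    se       p stars
1 eda_tonic     max agitated     1.13 0.279 5.5e-05   ***
```

18.6 % of surveys are rated agitated, the agitated fraction rises across
the clock blocks toward the evening (the planted sundowning gradient), and
the maximum tonic EDA level is 1.13 log-odds of agitation higher per
within-patient SD (Wald p ≈ 5e-5) after adjusting for time of day and
ambient temperature — the pipeline recovers the planted electrodermal
arousal.  The `analysis/` directory runs the same chain at full cohort
scale as numbered scripts (`01_simulate_cohort.R` … `04_report.R`), writing
their tables under `results/`.

## Package layout

* `R/sim-config.R`, `R/sim-cohort.R` — synthetic cohort generator.
* `R/streams.R` — stream data model, columnar text I/O, window extraction.
* `R/qc.R` — acceleration magnitude, heart-rate imputation, verdicts.
* `R/eda.R` — filtering, quality indicator, artifact interpolation,
  Bateman-kernel deconvolution (`src/nnls_bateman.cpp`).
* `R/features.R`, `R/surveys.R` — features, standardization, survey rules.
* `R/glmm.R` — marginal likelihood (Laplace + Gauss–Hermite oracle), model
  fitting, the per-feature screen.
* `R/report.R` — proportions by block, median-difference tables,
  coefficient tables.
* `vignettes/agitation-wearables-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator realism, limitations.
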