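---
title: "Methods: momentary agitation and wrist-wearable physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: momentary agitation and wrist-wearable physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agitsense)
```

## The question and the design

Agitation is among the most burdensome behavioral symptoms of dementia, and
ward staff can only rate it when they observe it.  `agitsense` implements a
momentary (experience-sampling) analysis that asks which wrist-wearable
physiological signals change *at the moment* a patient is rated agitated.
The design it encodes: nurses score short agitation surveys (PAS item
scores, RASS) at nine pseudorandom prompts per day between 08:45 and 20:45
with at least 50 minutes between prompts, plus spontaneous surveys when
agitation is observed; a wrist device records tri-axial acceleration
(32 Hz), heart rate derived from PPG (0.5 Hz, with low-quality samples
marked missing), electrodermal activity (256 Hz raw, 8 Hz after
preprocessing), and skin temperature (1 Hz); ward sensors record ambient
temperature.  Around each survey a 6-minute window — the median duration of
an agitation episode — is cut from every signal, summarized into a handful
of interpretable features, standardized within patient, and related to the
binary agitation outcomes with logistic mixed models.

Because the clinical recordings are not public, the package ships a
synthetic cohort generator that reproduces the *structure* of such a study
with known ground truth.  Every stage of the pipeline is validated against
that ground truth; the generator is itself first-class, tested code.

## Survey processing

Surveys within 5 minutes of the previously retained survey of the same
patient are duplicates and are removed (sequential scan, earlier survey
kept; a gap of exactly 5 minutes keeps both).  Outcomes are binarized from
the PAS items: overall agitation iff the item total exceeds 0, motor and
verbal agitation iff the motor and vocalization subscores exceed 0.  A
survey can be both motor- and verbal-agitated.  The clock is partitioned
into four blocks — 8–12, 12–16, 16–20, and the wrap-around 20–8 — used both
for describing the sundowning gradient and as the `time_group` fixed effect.

## Window extraction and quality control

Windows are half-open, `[t − 180 s, t + 180 s)`, on each stream's own
sample grid; the half-open convention avoids double-counting a boundary
sample (field protocols rarely state the convention either way).  Slots
with no recorded sample are explicit missing values, never silently
dropped, so "proportion missing" is well defined.

* **Acceleration.** The per-sample magnitude `sqrt(x^2 + y^2 + z^2)` (g) is
  the analysis signal.  No quality gate is applied beyond dropping fully
  empty windows — none is stated for this modality.
* **Heart rate.** Gaps shorter than 10 s are filled with a centered 10 s
  rolling median of originally valid neighbors; remaining interior gaps are
  cubic-spline interpolated; leading/trailing gaps stay missing (no
  extrapolation — there is no surrounding data).  A window with ≥ 50 %
  missing samples *before* imputation is dropped.  The drop rule is
  evaluated pre-imputation because it is the number of values that would
  need imputing that matters.
* **Skin temperature.** Samples are valid when present and inside the
  closed range 20–40 °C; a window with ≤ 50 % valid samples is dropped,
  and out-of-range samples are masked before feature extraction.
* **Electrodermal activity.** Raw 256 Hz windows are smoothed with a
  Savitzky–Golay filter (order 2, 1 s window — parameters chosen to
  suppress ADC quantization steps while preserving ~1 s SCR rise times)
  and decimated to 8 Hz.  A rule-based quality indicator stands in for the
  pretrained random-forest quality scores common in ambulatory EDA work
  (no such model ships with this package): the indicator is the fraction of clean 5 s
  segments, where a segment is unclean if it contains missing samples, any
  sample outside 0.05–60 µS, a slope above 10 µS/s, or is flat (range
  < 0.001 µS) for the whole 5 s.  The decision threshold is kept at 0.5:
  windows with an indicator strictly below 0.5 are dropped.  Unclean
  segments of kept windows are cubic-interpolated from flanking clean data
  (edges held at the nearest clean value).  Numeric agreement with
  model-based quality scores is not claimed — only the same 0.5
  keep/drop semantics.

## Electrodermal decomposition

The cleaned 8 Hz signal is decomposed into a slowly varying tonic level
(SCL) and a phasic component (SCRs) by deconvolution.  A single SCR is
modeled with the Bateman difference-of-exponentials impulse response
(`tau_rise` 0.75 s, `tau_decay` 2.0 s by default, unit peak; the overall
response then spans roughly 1–4 s).  The tonic is represented on a coarse
cubic B-spline basis (knots every 30 s) and initialized through the
per-10 s-segment troughs of the signal; the phasic component is a
nonnegative driver convolved with the kernel, estimated by nonnegative
ridge least squares (ridge 1e-6) on the residual.  The tie between tonic
level and a constant driver load is resolved by fitting the tonic first on
the troughs; one alternating refit of tonic and driver then tightens the
reconstruction.

Numerically, the discretized kernel is an exactly invertible two-pole
recursive filter, which gives (i) an O(n) exact unconstrained deconvolution
used to warm-start the solver and (ii) O(n) convolutions inside the
projected-FISTA nonnegative solver (compiled code).  On noiseless traces
generated with the package's own kernel the decomposition reconstructs the
signal to well under 0.01 µS RMSE and recovers planted impulse times and
amplitudes essentially exactly; a configuration flag (`kernel_mismatch`)
generates data with perturbed time constants for robustness probing.  The
solver reports non-convergence rather than passing silently; with the
default iteration budget (30 split across the passes) this matters only
for heavily artifact-laden windows.

## Features and standardization

Each kept window yields minimum, maximum, median, and sample SD
(denominator n − 1) of:
acceleration magnitude, heart rate, the cleaned electrodermal signal, its
tonic and phasic components, and skin temperature; skin temperature
additionally yields the OLS slope in °C/min (OLS chosen over an
endpoint difference for noise robustness; units are a package convention).
All features are then z-scored within patient across that patient's kept
windows (agitated and non-agitated pooled), so model coefficients are
log-odds per within-patient SD.  Zero-variance features for a patient give
missing z-scores and are excluded.  Patients contributing fewer than two
kept surveys for a modality are excluded from that modality's models only.

## The mixed models

For each feature and each outcome (overall, motor, verbal agitation) a
separate Bernoulli-logit GLMM is fitted with fixed effects intercept,
standardized feature, `time_group` (treatment contrasts, block 1
reference), and the modality-specific confounder — mean ambient temperature
over the window for electrodermal and skin-temperature features,
acceleration-magnitude SD for heart-rate features, none for acceleration —
plus a patient random intercept, `u_i ~ N(0, sigma_u^2)`.  Random slopes
are deliberately not used.  Continuous confounders are standardized within
patient like the features, so all coefficients share the per-SD scale
(this package standardizes them; pass raw values to change that).

The marginal likelihood integrates each patient's random intercept with a
sixth-order-corrected Laplace approximation: the usual mode-plus-curvature
term times the skewness/kurtosis correction factor
`1 + c4/(8 lambda^2) + (5 c3^2 + c6/2)/(24 lambda^3)` evaluated from the
exact derivatives of the Bernoulli-logit integrand at the mode.  The plain
Laplace value (as in standard mixed-model software) is available via
`correction = "none"`; the correction matters for weakly informative
clusters, where the plain approximation can be off by ~0.1 on the
log-likelihood.  For clusters so weak that the correction itself is
non-negligible (curvature scale `1/lambda` above ~0.45 or correction above
~5 %), the one-dimensional integral is instead evaluated by a wide
201-point Simpson rule, smoothly blended to keep the objective
differentiable.  Study-sized clusters (≳ 15 observations) never trigger
this refinement, so fitting stays at Laplace cost.  An independent adaptive
Gauss–Hermite oracle (25+ nodes, Golub–Welsch construction, centered and
scaled at the mode) is implemented purely for verification; across
randomized small instances the two agree to a few 1e-3 on the
log-likelihood, and the `sigma_u -> 0` limit reproduces plain logistic
regression exactly.

Optimization is BFGS on `(beta, log sigma_u)` (relative tolerance 1e-10,
500 iterations, restarts from `sigma_u` 0.1 and 1 on failure); standard
errors come from the inverse observed information at the optimum and
p-values from two-sided Wald tests, unadjusted for multiple testing — the
screen is exploratory by design.  Complete separation (any standardized
coefficient beyond ±10) and non-convergence are flagged, and flagged fits
carry no interpretation.

## The synthetic cohort generator

The generator emulates an experience-sampling ward study with known ground
truth.  Its defaults were chosen once to match the emulated design and its
descriptive anchors, then left alone:

* 30 patients × 7 days; device worn 08–21 h.
* Nine prompts/day in 08:45–20:45 with ≥ 50 min spread, drawn by the exact
  uniform construction over the constrained set (distributionally identical
  to rejection sampling, O(1) per day).
* Agitation bouts follow a piecewise-constant Poisson process over the
  clock blocks *intersected with the wear day*, base rate 1.2/h and
  sundowning multipliers (0.5, 1, 1.5, 2); durations are lognormal with
  median 6 min (sigma_log 0.5).  Restricting the process to the observed
  day is deliberate: nothing outside wear time is observable, and an
  around-the-clock block-4 hazard would flood the cohort with invisible
  night bouts.  With these values ~22 % of surveys are agitated and the
  block-wise proportion rises monotonically, mirroring the sundowning
  gradient.
* Bout types: motor 30 %, verbal 10 %, both 25 %, "none" 35 % (agitation
  without a motor or verbal subscore, e.g. aggression/resisting care only),
  giving a survey mix typical of ward cohorts (motor and both a few percent
  of surveys each, verbal rarer).  Spontaneous surveys
  fire at bout midpoints with probability 0.08.
* Signals: gravity-dominated acceleration with slow posture change and
  0.03 g noise; heart rate 72 bpm baseline with diurnal drift and AR(1)
  noise (SD 3 bpm); electrodermal activity as a smooth tonic around 2 µS
  plus a Bateman SCR train (2 SCR/min baseline, lognormal amplitudes
  ~0.3 µS) — the same kernel the decomposition assumes, so recovery tests
  have an exact forward model; skin temperature ~33 °C coupled negatively
  (−0.2 °C/°C) to the smooth ambient deviation.
* During bouts the autonomic signature ramps in with a 45 s time constant:
  tonic +0.3 µS, SCR rate +4/min, heart rate +5 bpm, skin temperature
  −0.4 °C, and (motor bouts) +0.15 g acceleration noise, scaled per bout
  type (verbal bouts weight the electrodermal channels, motor bouts the
  movement/cardiac channels).
* Missingness: 15 % nonwear per survey, 12 % per-sample heart-rate
  missingness plus a 20 % chance of a contiguous dropout covering 20–100 %
  of the window, 5 % electrodermal artifact segments, and occasional
  out-of-range skin-temperature spikes.

Everything is reproducible: the cohort is generated under seeds derived
deterministically from the single configured seed, so an identical
configuration yields a byte-identical cohort, and sensor samples for a
survey window are the same whether generated alone or within the cohort
loop.  At cohort scale, samples are generated only over the 6-minute survey
windows (plus margin); `synthesize_streams()` also produces full wear-day
streams for stream-level work, and the two share all generating code.

### What the generator does and does not emulate

It reproduces the sampling design, the missingness patterns the QC rules
target, the sundowning gradient, and a plantable autonomic signature with
known sign structure — which is exactly what is needed to verify the
pipeline end to end (a planted +EDA/+HR/−ST/+ACC-SD signature is recovered
with the correct signs in essentially every replicate cohort).  It does not
emulate real-world confounder structure (medication, care events, posture
changes correlated with mood), non-Bateman SCR shapes, autocorrelated
nonwear, or rater disagreement.  Passing tests therefore demonstrate the
pipeline's correctness and statistical calibration, not clinical validity
on real recordings.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen as the
smallest that make the statistical claims sharp: 20 noiseless traces for
the decomposition consistency check; 50 random small instances for the
Laplace/quadrature agreement; 500 null replicates at 25 patients × 20
surveys for Wald size (nominal 5 %, accepted 3–8 %); 200 replicates for
planted-parameter recovery; and 20 replicate cohorts at the full 30 × 7
design for the end-to-end direction-recovery check.  Degenerate inputs are
handled explicitly: empty windows drop with reason `no_data`; constant
series give SD 0 and slope 0; zero-variance features standardize to
missing; single-class outcomes and single-patient data refuse to fit; the
phasic *minimum* feature is ~0 in every window and drops out through the
zero-variance rule rather than producing spurious fits.

## Known limitations

The EDA quality indicator is a documented heuristic, not the original
pretrained model; absolute kept-window fractions will differ from the
original study even though the 0.5 threshold semantics match.  The
generator's heart-rate quality process yields higher kept fractions than
the published availability table, so per-modality patient counts are not
comparable — only rule behavior is.  Tonic/phasic identifiability rests on
the coarse-spline tie-break; pathological signals (sustained staircase
drifts) could shift mass between components.  And coefficient values from real
cohorts derive from private clinical data, so this package validates the
direction pattern and the machinery's calibration, not any particular
published point estimate.
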