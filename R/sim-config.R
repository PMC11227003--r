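#' Planted autonomic-activation effect profile
#'
#' Defines how an agitation episode perturbs each sensor modality in the
#' synthetic cohort, following the sympathetic-activation pattern expected
#' clinically: electrodermal tonic level and phasic (skin conductance
#' response) rate go up, heart rate goes up, distal skin temperature goes
#' down, and motor-type episodes add acceleration variability.
#'
#' Per-type scaling multiplies the deltas so that motor episodes weight the
#' movement/cardiac channels and verbal episodes weight the electrodermal
#' channels; "none"-type episodes (agitation without a motor or verbal
#' subscore, e.g. aggression/resistiveness only) get attenuated autonomic
#' effects and no movement effect.
#'
#' @param delta_tonic_level increase of tonic skin conductance level, uS.
#' @param delta_phasic_rate increase of SCR event rate, peaks/min.
#' @param delta_hr increase of heart rate, beats/min.
#' @param delta_st change of skin temperature, degC (non-positive by
#'   convention: distal vasoconstriction).
#' @param delta_acc_sd extra acceleration noise SD during motor episodes, g.
#' @param type_scaling named list of per-episode-type multipliers, each a
#'   vector with entries \code{acc}, \code{hr}, \code{eda}, \code{st}.
#' @return an \code{effect_profile} list.
#' @export
effect_profile <- function(delta_tonic_level = 0.3,
                           delta_phasic_rate = 4,
                           delta_hr = 5,
                           delta_st = -0.4,
                           delta_acc_sd = 0.15,
                           type_scaling = list(
                             motor  = c(acc = 1.0, hr = 1.3, eda = 0.7, st = 1.0),
                             verbal = c(acc = 0.0, hr = 0.7, eda = 1.5, st = 1.0),
                             both   = c(acc = 1.0, hr = 1.2, eda = 1.2, st = 1.2),
                             none   = c(acc = 0.0, hr = 0.5, eda = 0.5, st = 0.5))) {
  stopifnot(is.finite(delta_tonic_level), is.finite(delta_phasic_rate),
            is.finite(delta_hr), is.finite(delta_st), is.finite(delta_acc_sd),
            delta_st <= 0)
  stopifnot(all(c("motor", "verbal", "both", "none") %in% names(type_scaling)))
  structure(list(delta_tonic_level = delta_tonic_level,
                 delta_phasic_rate = delta_phasic_rate,
                 delta_hr = delta_hr, delta_st = delta_st,
                 delta_acc_sd = delta_acc_sd, type_scaling = type_scaling),
            class = "effect_profile")
}

#' Simulation configuration for the synthetic ward cohort
#'
#' Encodes the study design being emulated: ~30 ward patients observed ~1
#' week each, nine pseudorandom survey prompts per day between 08:45 and
#' 20:45 with a minimum 50-minute spread (plus spontaneous surveys during
#' episodes), sundowning (an episode hazard increasing across the four
#' clock blocks 8-12 / 12-16 / 16-20 / 20-8), wear-time sensor streams with
#' nonwear and missingness, and agitation episodes that perturb the signals
#' according to the \code{\link{effect_profile}}.
#'
#' @param n_patients number of patients.
#' @param days_per_patient days of inclusion per patient.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @param episode_base_rate baseline rate of agitation bouts, episodes/hour
#'   during the observed (wear-time) day, multiplied by the block-specific
#'   sundowning multiplier.  Bouts are short (median 6 min), so the momentary
#'   agitation prevalence at a prompt is roughly rate x mean duration.
#' @param sundowning_multipliers positive multipliers for clock blocks
#'   1 (8-12 h), 2 (12-16 h), 3 (16-20 h), 4 (20-8 h).
#' @param motor_fraction,verbal_fraction,both_fraction episode-type mix;
#'   the residual probability is "none"-type (neither motor nor verbal
#'   subscore positive).
#' @param effect_profile an \code{\link{effect_profile}}.
#' @param spontaneous_rate probability that an episode triggers a
#'   spontaneous survey at its midpoint.
#' @param nonwear_prob probability that a survey window has no wearable data
#'   (device refused/not worn); ambient temperature is unaffected.
#' @param hr_missing_prob per-sample probability that the 0.5 Hz heart-rate
#'   series is flagged low-quality (missing).
#' @param hr_dropout_prob probability that a window additionally contains one
#'   contiguous heart-rate dropout of random length (20-100\% of the window).
#' @param eda_artifact_prob probability that a window contains one 5-20 s
#'   electrodermal artifact segment (rail-high or zero).
#' @param st_spike_prob per-sample probability of a physically implausible
#'   skin-temperature reading (outside 20-40 degC).
#' @param acc_hz,hr_hz,eda_hz,st_hz,ambient_hz sampling rates, Hz.  The
#'   electrodermal channel may be emitted raw at 256 Hz or already at the
#'   8 Hz analysis rate.
#' @param wear_start_hour,wear_end_hour daily wear span (device on after
#'   morning care, off before bed).
#' @param hr_baseline,eda_tonic_level,scr_rate_baseline,st_baseline,
#'   ambient_baseline physiological baselines (bpm, uS, SCR/min, degC, degC).
#' @param acc_noise_sd,hr_noise_sd,st_noise_sd baseline sensor noise SDs.
#' @param ambient_coupling degC of skin-temperature change per degC of
#'   ambient deviation from its baseline.
#' @param tau_rise,tau_decay Bateman kernel time constants, s, shared by the
#'   generator's forward model and (by default) the decomposition.
#' @param kernel_mismatch if \code{TRUE}, the generator uses perturbed time
#'   constants so decomposition robustness can be probed.
#' @param episode_ramp_tau time constant, s, of the exponential onset/offset
#'   of episode effects on the physiology.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_patients = 30,
                       days_per_patient = 7,
                       seed = 1,
                       episode_base_rate = 1.2,
                       sundowning_multipliers = c(0.5, 1, 1.5, 2),
                       motor_fraction = 0.30,
                       verbal_fraction = 0.10,
                       both_fraction = 0.25,
                       effect_profile = agitsense::effect_profile(),
                       spontaneous_rate = 0.08,
                       nonwear_prob = 0.15,
                       hr_missing_prob = 0.12,
                       hr_dropout_prob = 0.20,
                       eda_artifact_prob = 0.05,
                       st_spike_prob = 0.002,
                       acc_hz = 32, hr_hz = 0.5, eda_hz = 8,
                       st_hz = 1, ambient_hz = 1,
                       wear_start_hour = 8, wear_end_hour = 21,
                       hr_baseline = 72, eda_tonic_level = 2,
                       scr_rate_baseline = 2, st_baseline = 33,
                       ambient_baseline = 22,
                       acc_noise_sd = 0.03, hr_noise_sd = 3, st_noise_sd = 0.05,
                       ambient_coupling = -0.2,
                       tau_rise = 0.75, tau_decay = 2.0,
                       kernel_mismatch = FALSE,
                       episode_ramp_tau = 45) {
  fracs <- c(motor_fraction, verbal_fraction, both_fraction)
  stopifnot(n_patients >= 1, days_per_patient >= 1,
            episode_base_rate >= 0,
            length(sundowning_multipliers) == 4L,
            all(sundowning_multipliers > 0),
            all(fracs >= 0), sum(fracs) <= 1,
            nonwear_prob >= 0, nonwear_prob <= 1,
            hr_missing_prob >= 0, hr_missing_prob <= 1,
            spontaneous_rate >= 0, spontaneous_rate <= 1,
            eda_hz %in% c(8, 256),
            0 < tau_rise, tau_rise < tau_decay,
            inherits(effect_profile, "effect_profile"))
  cfg <- as.list(environment())
  cfg$fracs <- NULL
  structure(cfg, class = "sim_config")
}

# small deterministic sub-seed derivation so per-unit generation is
# reproducible regardless of call order; stays below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed %% 100000, ...)
  h <- 0
  for (p in parts) h <- (h * 131 + as.numeric(p) + 1) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
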