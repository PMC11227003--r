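#' Generate the five sensor windows around one survey
#'
#' Synthesizes the patient's streams over the 6-minute window (plus margin)
#' under a seed derived from the cohort seed and the survey identity, then
#' extracts the survey-centered window per modality.  Samples outside the
#' daily wear span are missing (device off), as is everything but ambient
#' temperature for nonwear surveys.
#'
#' @param config a \code{\link{sim_config}}.
#' @param episodes episode truth for this patient.
#' @param survey one row of the cohort survey table.
#' @param p_index patient index (for seed derivation).
#' @return named list of \code{feature_window}s (acc, hr, eda, st, ambient).
#' @export
generate_survey_windows <- function(config, episodes, survey, p_index) {
  t_c <- survey$timestamp
  day <- floor(t_c / 86400) + 1
  day0 <- (day - 1) * 86400
  wear <- day0 + c(config$wear_start_hour, config$wear_end_hour) * 3600
  span <- c(t_c - 190, t_c + 190)
  gen_span <- c(max(span[1], wear[1]), min(span[2], wear[2]))
  seed <- derive_seed(config$seed, p_index, round(t_c))
  streams <- if (gen_span[2] - gen_span[1] > 2) {
    synthesize_streams(config, episodes, survey$patient_id, day,
                       t_start = gen_span[1], t_end = gen_span[2], seed = seed)
  } else NULL
  out <- list()
  for (m in c("acc", "hr", "eda", "st", "ambient")) {
    fs <- config[[paste0(m, "_hz")]]
    if (m == "ambient" || (!is.null(streams) && !isTRUE(survey$nonwear))) {
      st_m <- if (m == "ambient" && is.null(streams)) {
        # ward sensor runs around the clock
        with_seed(seed, {
          tt <- span[1] + seq(0, by = 1 / fs, length.out = floor(380 * fs))
          sensor_stream(survey$patient_id, "ambient", fs, span[1],
                        config$ambient_baseline + ambient_deviation(tt) +
                          stats::rnorm(length(tt), 0, 0.05))
        })
      } else streams[[m]]
      out[[m]] <- extract_window(st_m, t_c, survey_id = survey$survey_id)
    } else {
      # nonwear / fully off-wear window: every slot missing
      n_slots <- as.integer(round(360 * fs))
      empty <- if (m == "acc") matrix(NA_real_, n_slots, 3) else rep(NA_real_, n_slots)
      w <- structure(list(survey_id = survey$survey_id,
                          patient_id = survey$patient_id, modality = m,
                          t_center = t_c, duration = 360, sampling_rate = fs,
                          times = t_c - 180 + (seq_len(n_slots) - 1) / fs,
                          samples = empty, n_slots = n_slots,
                          n_missing = n_slots, quality_verdict = "kept",
                          drop_reason = NA_character_),
                     class = "feature_window")
      out[[m]] <- w
    }
  }
  out
}

# run modality QC + feature extraction for the windows of one survey;
# features come back as a named numeric vector ("signal|feature") so the
# cohort loop can assemble one data.frame at the end
process_survey_windows <- function(wins, rules, kernel, basis = NULL) {
  vals <- numeric(0)
  verdicts <- c(acc = NA_character_, hr = NA_character_, eda = NA_character_,
                st = NA_character_)
  grab <- function(signal, values, times = NULL, slope = FALSE) {
    if (sum(!is.na(values)) < 2L) return(NULL)
    fv <- extract_features(values, times = times, slope = slope)
    names(fv) <- paste(signal, names(fv), sep = "|")
    fv
  }
  acc_sd <- NA_real_
  ## acceleration: magnitude series, no quality gate beyond non-empty
  w <- acc_window_series(wins$acc)
  verdicts["acc"] <- w$quality_verdict
  if (w$quality_verdict == "kept") {
    f <- grab("acc_magnitude", w$samples)
    if (!is.null(f)) {
      vals <- c(vals, f)
      acc_sd <- f[["acc_magnitude|sd"]]
    }
  }
  ## heart rate: drop on pre-imputation missingness, then impute
  w <- impute_hr_window(wins$hr, rules)
  verdicts["hr"] <- hr_window_verdict(w, rules)
  if (verdicts["hr"] == "kept") {
    f <- grab("hr", w$samples)
    if (is.null(f)) verdicts["hr"] <- "dropped" else vals <- c(vals, f)
  }
  ## electrodermal: quality gate, artifact interpolation, decomposition
  w <- preprocess_eda_window(wins$eda, rules, kernel, basis = basis)
  verdicts["eda"] <- w$quality_verdict
  if (w$quality_verdict == "kept") {
    vals <- c(vals, grab("eda_full", w$cleaned), grab("eda_tonic", w$tonic),
              grab("eda_phasic", w$phasic))
  }
  ## skin temperature: range validity rule, slope feature
  w <- wins$st
  verdicts["st"] <- st_window_verdict(w, rules)
  if (verdicts["st"] == "kept") {
    w <- st_mask_invalid(w, rules)
    f <- grab("st", w$samples, times = w$times, slope = TRUE)
    if (is.null(f)) verdicts["st"] <- "dropped" else vals <- c(vals, f)
  }
  ambient_mean <- if (sum(!is.na(wins$ambient$samples)) >= 2L)
    mean(wins$ambient$samples, na.rm = TRUE) else NA_real_
  list(values = vals,
       confounders = c(ambient_mean = ambient_mean, acc_sd = acc_sd),
       verdicts = verdicts)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Survey cleaning (deduplication, outcome binarization, time blocks),
#' window generation and per-modality quality control, feature extraction,
#' within-patient standardization, per-modality patient inclusion, and
#' assembly of the analysis-ready model rows.
#'
#' @param cohort result of \code{\link{simulate_cohort}} (or a
#'   \code{\link{sim_config}}, which is simulated first).
#' @param rules a \code{\link{qc_rules}}.
#' @param kernel Bateman kernel for the electrodermal decomposition;
#'   defaults to the configured time constants at 8 Hz.
#' @return list with \code{surveys} (cleaned, with outcomes and time
#'   blocks), \code{features} (long, with \code{z}), \code{model_rows}
#'   (features joined with outcomes and standardized confounders),
#'   \code{verdicts} (per survey x modality), \code{config}.
#' @export
run_pipeline <- function(cohort, rules = qc_rules(), kernel = NULL) {
  if (inherits(cohort, "sim_config")) cohort <- simulate_cohort(cohort)
  config <- cohort$config
  if (is.null(kernel))
    kernel <- bateman_kernel(config$tau_rise, config$tau_decay, fs = 8)
  basis <- tonic_basis(as.integer(360 * 8), fs = 8)
  sv <- deduplicate(cohort$surveys)
  sv <- binarize_outcomes(sv)
  sv$time_group <- assign_time_group(sv$timestamp)
  p_index <- match(sv$patient_id, sprintf("P%02d", seq_len(config$n_patients)))
  ep_by_patient <- split(cohort$episodes, cohort$episodes$patient_id)
  feats <- vector("list", nrow(sv))
  conf <- matrix(NA_real_, nrow(sv), 2,
                 dimnames = list(NULL, c("ambient_mean", "acc_sd")))
  verd <- matrix(NA_character_, nrow(sv), 4,
                 dimnames = list(NULL, c("acc", "hr", "eda", "st")))
  for (i in seq_len(nrow(sv))) {
    ep <- ep_by_patient[[sv$patient_id[i]]]
    wins <- generate_survey_windows(config, ep, sv[i, ], p_index[i])
    res <- process_survey_windows(wins, rules, kernel, basis)
    feats[[i]] <- res$values
    conf[i, ] <- res$confounders
    verd[i, ] <- res$verdicts
  }
  n_per <- lengths(feats)
  all_names <- unlist(lapply(feats, names), use.names = FALSE)
  sig_feat <- matrix(unlist(strsplit(all_names, "|", fixed = TRUE)), ncol = 2,
                     byrow = TRUE)
  features <- if (sum(n_per) > 0) data.frame(
    survey_id = rep(sv$survey_id, n_per),
    patient_id = rep(sv$patient_id, n_per),
    modality = sub("_.*$", "", sig_feat[, 1]),
    signal = sig_feat[, 1],
    feature = sig_feat[, 2],
    value = unlist(feats, use.names = FALSE),
    stringsAsFactors = FALSE) else NULL
  verdicts <- data.frame(survey_id = sv$survey_id, verd,
                         stringsAsFactors = FALSE)
  sv$ambient_mean <- conf[, "ambient_mean"]
  sv$acc_sd <- conf[, "acc_sd"]
  if (is.null(features) || nrow(features) == 0L)
    return(list(surveys = sv, features = NULL, model_rows = NULL,
                verdicts = verdicts, config = config))
  # per-modality inclusion: a patient needs >= 2 kept surveys in a modality
  features <- apply_inclusion_rules(features)
  features <- standardize_within_patient(features)
  # standardize the confounders within patient as well (comparability of
  # coefficients across patients)
  for (cc in c("ambient_mean", "acc_sd")) {
    cf <- data.frame(patient_id = sv$patient_id, signal = "conf",
                     feature = cc, value = sv[[cc]])
    sv[[paste0("z_", cc)]] <- standardize_within_patient(cf)$z
  }
  keep_cols <- c("survey_id", "agitated", "motor_agitated", "verbal_agitated",
                 "time_group", "z_ambient_mean", "z_acc_sd")
  rows <- merge(features, sv[keep_cols], by = "survey_id", sort = FALSE)
  list(surveys = sv, features = features, model_rows = rows,
       verdicts = verdicts, config = config)
}
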