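#' Generate one day's pseudorandom survey prompt schedule
#'
#' Nine prompt times between 08:45 and 20:45 with every pairwise gap at
#' least 50 minutes, drawn uniformly over the constrained set (the nine
#' ordered gaps beyond the mandatory 50-minute spacings are distributed
#' uniformly over the 320 minutes of slack).
#'
#' Uses the current RNG state; wrap in \code{set.seed()} for reproducibility.
#'
#' @param day study day (1-based); timestamps are offset by
#'   \code{(day - 1) * 86400} seconds.
#' @return sorted numeric vector of 9 timestamps (seconds since midnight of
#'   study day 1).
#' @export
generate_prompt_schedule <- function(day = 1) {
  span <- (20.75 - 8.75) * 3600          # 43200 s
  min_gap <- 50 * 60                     # 3000 s
  slack <- span - 8 * min_gap            # 19200 s
  u <- sort(stats::runif(9, 0, slack))
  t <- 8.75 * 3600 + u + min_gap * (0:8)
  t + (day - 1) * 86400
}

#' Clock block of the day
#'
#' Partition of the 24 h clock used both for the sundowning hazard and as
#' the \code{time_group} fixed effect: 1 = 8-12 h, 2 = 12-16 h, 3 = 16-20 h,
#' 4 = 20-8 h (wrap-around).
#'
#' @param timestamp seconds since midnight of day 1 (any day; clock time is
#'   taken modulo 86400).
#' @return integer block in 1..4.
#' @export
assign_time_group <- function(timestamp) {
  h <- (timestamp %% 86400) / 3600
  ifelse(h >= 8 & h < 12, 1L,
         ifelse(h >= 12 & h < 16, 2L,
                ifelse(h >= 16 & h < 20, 3L, 4L)))
}

#' Simulate agitation episodes for one patient-day
#'
#' Episodes arise from a piecewise-constant-rate Poisson process over the
#' four clock blocks intersected with the observed wear-time day
#' (rate = \code{episode_base_rate} x block multiplier, episodes/hour),
#' with lognormal durations (median 6 min, sigma_log 0.5) and a categorical
#' type (motor / verbal / both / none).  Overlapping draws are resolved by
#' keeping the earlier episode.
#'
#' @param config a \code{\link{sim_config}}.
#' @param patient_id patient identifier.
#' @param day study day (1-based).
#' @return data.frame with columns patient_id, start, end, type
#'   (episode ground truth; empty if no episodes).
#' @export
simulate_episodes <- function(config, patient_id, day) {
  day0 <- (day - 1) * 86400
  # block segments intersected with the observed (wear-time) day: agitation
  # is only generated while it can be observed and sensed
  blocks <- list(c(8, 12, 1), c(12, 16, 2), c(16, 20, 3), c(20, 24, 4), c(0, 8, 4))
  w0 <- config$wear_start_hour; w1 <- config$wear_end_hour
  segs <- list()
  for (b in blocks) {
    lo <- max(b[1], w0); hi <- min(b[2], w1)
    if (hi > lo) segs[[length(segs) + 1L]] <- c(lo, hi, b[3])
  }
  starts <- numeric(0)
  for (s in segs) {
    len_h <- s[2] - s[1]
    rate <- config$episode_base_rate * config$sundowning_multipliers[s[3]]
    n <- stats::rpois(1, rate * len_h)
    if (n > 0) starts <- c(starts, day0 + stats::runif(n, s[1], s[2]) * 3600)
  }
  if (length(starts) == 0L)
    return(data.frame(patient_id = character(0), start = numeric(0),
                      end = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  starts <- sort(starts)
  durations <- stats::rlnorm(length(starts), meanlog = log(360), sdlog = 0.5)
  p_none <- 1 - config$motor_fraction - config$verbal_fraction - config$both_fraction
  types <- sample(c("motor", "verbal", "both", "none"), length(starts),
                  replace = TRUE,
                  prob = c(config$motor_fraction, config$verbal_fraction,
                           config$both_fraction, p_none))
  ep <- data.frame(patient_id = patient_id, start = starts,
                   end = starts + durations, type = types,
                   stringsAsFactors = FALSE)
  # enforce non-overlap: keep the earlier episode
  keep <- rep(TRUE, nrow(ep))
  last_end <- -Inf
  for (i in seq_len(nrow(ep))) {
    if (ep$start[i] < last_end) keep[i] <- FALSE
    else last_end <- ep$end[i]
  }
  ep[keep, , drop = FALSE]
}

# episode effect envelope at given times for one modality channel
# ("acc", "hr", "eda", "st"): exponential onset during the episode,
# exponential offset after it, scaled by the episode-type multiplier.
episode_envelope <- function(times, episodes, profile, channel, ramp_tau) {
  env <- numeric(length(times))
  if (is.null(episodes) || nrow(episodes) == 0L) return(env)
  tau_dn <- 1.3 * ramp_tau
  # only episodes whose effect (incl. decay tail) reaches the span matter
  t_lo <- times[1]; t_hi <- times[length(times)]
  rel <- episodes$start <= t_hi & episodes$end >= t_lo - 8 * tau_dn
  episodes <- episodes[rel, , drop = FALSE]
  if (nrow(episodes) == 0L) return(env)
  for (i in seq_len(nrow(episodes))) {
    sc <- profile$type_scaling[[episodes$type[i]]][[channel]]
    if (sc == 0) next
    s <- episodes$start[i]; e <- episodes$end[i]
    shape <- numeric(length(times))
    inside <- times >= s & times <= e
    shape[inside] <- 1 - exp(-(times[inside] - s) / ramp_tau)
    after <- times > e
    peak <- 1 - exp(-(e - s) / ramp_tau)
    shape[after] <- peak * exp(-(times[after] - e) / tau_dn)
    env <- pmax(env, sc * shape)
  }
  env
}

# deterministic smooth ambient deviation from baseline (degC), peak 15:00
ambient_deviation <- function(times) {
  1.5 * cos(2 * pi * ((times %% 86400) - 54000) / 86400)
}

#' Synthesize sensor streams for one patient over a time span
#'
#' Generates the per-modality baselines (ACC magnitude near 1 g with slow
#' posture change, heart rate with diurnal drift and AR(1) noise,
#' electrodermal activity as a smooth tonic level plus a Bateman-kernel SCR
#' train, skin temperature near 31-34 degC coupled negatively to ambient
#' deviation) and superimposes the \code{\link{effect_profile}} deltas during
#' the given episodes.  Missingness is applied last (heart-rate samples
#' flagged missing; optional contiguous dropout; optional electrodermal
#' artifact segment; occasional out-of-range skin-temperature spikes).
#'
#' @param config a \code{\link{sim_config}}.
#' @param episodes episode data.frame from \code{\link{simulate_episodes}}
#'   (only rows for this patient matter).
#' @param patient_id patient identifier.
#' @param day study day, used for the default span (wear time that day).
#' @param t_start,t_end span to generate, seconds since midnight of day 1;
#'   default is the configured wear time of \code{day}.
#' @param seed optional integer; if given, generation happens under this
#'   seed without disturbing the caller's RNG state.
#' @return named list of \code{\link{sensor_stream}}s:
#'   \code{acc}, \code{hr}, \code{eda}, \code{st}, \code{ambient}.
#' @export
synthesize_streams <- function(config, episodes, patient_id, day = 1,
                               t_start = NULL, t_end = NULL, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, synthesize_streams(
    config, episodes, patient_id, day, t_start, t_end, seed = NULL)))
  day0 <- (day - 1) * 86400
  if (is.null(t_start)) t_start <- day0 + config$wear_start_hour * 3600
  if (is.null(t_end)) t_end <- day0 + config$wear_end_hour * 3600
  stopifnot(t_end > t_start)
  prof <- config$effect_profile
  grid <- function(fs) t_start + seq(0, by = 1 / fs,
                                     length.out = floor((t_end - t_start) * fs))

  ## ambient temperature (ward sensor, unaffected by wear)
  t_amb <- grid(config$ambient_hz)
  ambient <- config$ambient_baseline + ambient_deviation(t_amb) +
    stats::rnorm(length(t_amb), 0, 0.05)

  ## accelerometer: gravity vector with slow posture change + noise,
  ## episode effect = extra axis noise (movement)
  t_acc <- grid(config$acc_hz)
  ph <- stats::runif(6, 0, 2 * pi)
  theta <- 0.25 * sin(2 * pi * t_acc / 700 + ph[1])
  psi <- 0.25 * sin(2 * pi * t_acc / 1100 + ph[2])
  env_acc <- episode_envelope(t_acc, episodes, prof, "acc", config$episode_ramp_tau)
  sd_acc <- sqrt(config$acc_noise_sd^2 + (prof$delta_acc_sd * env_acc)^2)
  n_acc <- length(t_acc)
  acc <- cbind(x = sin(theta) + stats::rnorm(n_acc, 0, sd_acc),
               y = sin(psi) * cos(theta) + stats::rnorm(n_acc, 0, sd_acc),
               z = cos(psi) * cos(theta) + stats::rnorm(n_acc, 0, sd_acc))

  ## heart rate: baseline + diurnal + AR(1) + episode delta; missingness last
  t_hr <- grid(config$hr_hz)
  n_hr <- length(t_hr)
  phi_ar <- 0.95
  ar <- stats::filter(stats::rnorm(n_hr, 0, config$hr_noise_sd * sqrt(1 - phi_ar^2)),
                      phi_ar, method = "recursive")
  env_hr <- episode_envelope(t_hr, episodes, prof, "hr", config$episode_ramp_tau)
  hr <- config$hr_baseline + 3 * cos(2 * pi * ((t_hr %% 86400) - 57600) / 86400) +
    as.numeric(ar) + prof$delta_hr * env_hr
  hr[stats::runif(n_hr) < config$hr_missing_prob] <- NA_real_
  if (stats::runif(1) < config$hr_dropout_prob && n_hr > 4L) {
    len <- max(1L, floor(stats::runif(1, 0.2, 1.0) * n_hr))
    at <- sample.int(n_hr - len + 1L, 1L)
    hr[at:(at + len - 1L)] <- NA_real_
  }

  ## electrodermal activity: tonic + Bateman SCR train (+ optional artifact)
  fs_eda <- config$eda_hz
  t_eda <- grid(fs_eda)
  env_eda <- episode_envelope(t_eda, episodes, prof, "eda", config$episode_ramp_tau)
  tonic <- config$eda_tonic_level + 0.3 * sin(2 * pi * (t_eda %% 86400) / 1800 + ph[3]) +
    prof$delta_tonic_level * env_eda * (1 + 0.25 * sin(2 * pi * t_eda / 90 + ph[4]))
  taus <- c(config$tau_rise, config$tau_decay)
  if (isTRUE(config$kernel_mismatch)) taus <- taus * 1.25
  kern <- bateman_kernel(tau_rise = taus[1], tau_decay = taus[2], fs = fs_eda)
  # SCR events: inhomogeneous Poisson by thinning, starting slightly before
  # the span so responses in flight at t_start are represented
  max_scale <- max(vapply(prof$type_scaling, `[[`, numeric(1), "eda"))
  max_rate <- (config$scr_rate_baseline +
                 max(0, prof$delta_phasic_rate) * max(1e-9, max_scale)) / 60
  lead <- 15
  n_cand <- stats::rpois(1, max_rate * (t_end - t_start + lead))
  phasic <- numeric(length(t_eda))
  if (n_cand > 0) {
    tc <- sort(stats::runif(n_cand, t_start - lead, t_end))
    env_at <- episode_envelope(tc, episodes, prof, "eda", config$episode_ramp_tau)
    rate_at <- (config$scr_rate_baseline + prof$delta_phasic_rate * env_at) / 60
    keep <- stats::runif(n_cand) < rate_at / max_rate
    tc <- tc[keep]
    if (length(tc) > 0) {
      amps <- stats::rlnorm(length(tc), meanlog = log(0.3), sdlog = 0.4)
      phasic <- scr_train(t_eda, tc, amps, kern$values, fs_eda)
    }
  }
  eda <- tonic + phasic
  if (stats::runif(1) < config$eda_artifact_prob && length(eda) > fs_eda * 25) {
    len <- floor(stats::runif(1, 5, 20) * fs_eda)
    at <- sample.int(length(eda) - len + 1L, 1L)
    eda[at:(at + len - 1L)] <- if (stats::runif(1) < 0.5) 80 else 0.001
  }
  if (fs_eda == 256) eda <- round(eda / 0.005) * 0.005  # ADC quantization

  ## skin temperature: baseline - ambient coupling + slow drift + episode delta
  t_st <- grid(config$st_hz)
  env_st <- episode_envelope(t_st, episodes, prof, "st", config$episode_ramp_tau)
  st <- config$st_baseline + config$ambient_coupling * ambient_deviation(t_st) +
    0.2 * sin(2 * pi * (t_st %% 86400) / 3600 + ph[5]) +
    prof$delta_st * env_st + stats::rnorm(length(t_st), 0, config$st_noise_sd)
  spikes <- stats::runif(length(st)) < config$st_spike_prob
  st[spikes] <- sample(c(15, 45), sum(spikes), replace = TRUE)

  list(acc = sensor_stream(patient_id, "acc", config$acc_hz, t_start, acc),
       hr = sensor_stream(patient_id, "hr", config$hr_hz, t_start, hr),
       eda = sensor_stream(patient_id, "eda", fs_eda, t_start, eda),
       st = sensor_stream(patient_id, "st", config$st_hz, t_start, st),
       ambient = sensor_stream(patient_id, "ambient", config$ambient_hz,
                               t_start, ambient))
}

# add amp * kernel at each event time onto the sampling grid
scr_train <- function(times, event_times, amps, kernel_values, fs) {
  out <- numeric(length(times))
  kl <- length(kernel_values)
  t0 <- times[1]
  for (j in seq_along(event_times)) {
    # first grid index at or after the event
    i0 <- ceiling((event_times[j] - t0) * fs - 1e-9)
    offset <- (t0 + i0 / fs) - event_times[j]   # in [0, 1/fs)
    idx <- i0 + seq_len(kl) - 1L
    ok <- idx >= 0L & idx < length(times)
    if (!any(ok)) next
    # kernel evaluated at the grid offsets (shift-invariant up to sub-sample)
    out[idx[ok] + 1L] <- out[idx[ok] + 1L] + amps[j] * kernel_values[ok]
  }
  out
}

#' Score surveys from the prompt schedule and episode ground truth
#'
#' Prompted surveys are scored from episode overlap at the prompt time: the
#' PAS motor item is positive iff a motor or both-type episode overlaps, the
#' vocalization item iff a verbal or both-type episode overlaps, and the
#' aggression item for "none"-type episodes (agitation without a motor or
#' verbal subscore).  Spontaneous surveys fire at episode midpoints with
#' probability \code{spontaneous_rate}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param episodes episode data.frame for this patient-day.
#' @param schedule prompt timestamps from \code{\link{generate_prompt_schedule}}.
#' @param patient_id patient identifier.
#' @return data.frame with columns patient_id, timestamp, prompted,
#'   pas_vocal, pas_motor, pas_aggr, pas_resist, rass, nonwear.
#' @export
emit_surveys <- function(config, episodes, schedule, patient_id) {
  times <- schedule
  prompted <- rep(TRUE, length(times))
  if (!is.null(episodes) && nrow(episodes) > 0 && config$spontaneous_rate > 0) {
    fire <- stats::runif(nrow(episodes)) < config$spontaneous_rate
    if (any(fire)) {
      mid <- (episodes$start[fire] + episodes$end[fire]) / 2
      times <- c(times, mid)
      prompted <- c(prompted, rep(FALSE, length(mid)))
    }
  }
  o <- order(times)
  times <- times[o]; prompted <- prompted[o]
  n <- length(times)
  severity <- function(k) 1L + stats::rbinom(k, 3L, 0.4)
  vocal <- motor <- aggr <- resist <- integer(n)
  for (i in seq_len(n)) {
    if (is.null(episodes) || nrow(episodes) == 0L) next
    hit <- episodes$start <= times[i] & episodes$end >= times[i]
    if (!any(hit)) next
    type <- episodes$type[which(hit)[1]]
    if (type %in% c("motor", "both")) motor[i] <- severity(1L)
    if (type %in% c("verbal", "both")) vocal[i] <- severity(1L)
    if (type == "none") aggr[i] <- severity(1L)
  }
  any_ag <- (vocal + motor + aggr + resist) > 0
  rass <- integer(n)
  rass[any_ag] <- sample(1:3, sum(any_ag), replace = TRUE)
  rass[!any_ag] <- sample(c(-1L, 0L, 0L), sum(!any_ag), replace = TRUE)
  data.frame(patient_id = patient_id, timestamp = times, prompted = prompted,
             pas_vocal = vocal, pas_motor = motor, pas_aggr = aggr,
             pas_resist = resist, rass = rass,
             nonwear = stats::runif(n) < config$nonwear_prob,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic ward cohort
#'
#' Runs schedule, episode, and survey generation for every patient-day under
#' seeds derived deterministically from \code{config$seed}, so the cohort is
#' byte-identical across runs with the same configuration.  Sensor samples
#' are generated lazily (per survey window, again under derived seeds) by
#' \code{\link{generate_survey_windows}}; use
#' \code{\link{synthesize_streams}} directly for full-day streams.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{config}, \code{surveys} (one row per survey, with
#'   survey_id), and \code{episodes} (ground truth).
#' @export
simulate_cohort <- function(config) {
  surveys <- list(); episodes <- list(); k <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (day in seq_len(config$days_per_patient)) {
      k <- k + 1L
      res <- with_seed(derive_seed(config$seed, p, day), {
        sched <- generate_prompt_schedule(day)
        ep <- simulate_episodes(config, pid, day)
        sv <- emit_surveys(config, ep, sched, pid)
        list(ep = ep, sv = sv)
      })
      surveys[[k]] <- res$sv
      episodes[[k]] <- res$ep
    }
  }
  surveys <- do.call(rbind, surveys)
  episodes <- do.call(rbind, episodes)
  surveys$survey_id <- sprintf("S%05d", seq_len(nrow(surveys)))
  rownames(surveys) <- NULL
  list(config = config, surveys = surveys, episodes = episodes)
}

#' Write a cohort to disk
#'
#' One columnar text file per patient/day/modality (dialect of
#' \code{\link{write_stream}}), a surveys file, an episode ground-truth
#' file, and a JSON manifest recording the configuration and seed.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @param patients,days restrict the (slow, large) stream files to these
#'   patient indices / days; surveys, episodes and manifest always cover the
#'   whole cohort.  Defaults write streams for all patient-days.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, patients = NULL, days = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  utils::write.csv(cohort$surveys, file.path(dir, "surveys.csv"), row.names = FALSE)
  utils::write.csv(cohort$episodes, file.path(dir, "episodes.csv"), row.names = FALSE)
  manifest <- unclass(cfg)
  manifest$effect_profile <- unclass(manifest$effect_profile)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(patients)) patients <- seq_len(cfg$n_patients)
  if (is.null(days)) days <- seq_len(cfg$days_per_patient)
  for (p in patients) {
    pid <- sprintf("P%02d", p)
    for (day in days) {
      ep <- cohort$episodes[cohort$episodes$patient_id == pid, , drop = FALSE]
      streams <- synthesize_streams(cfg, ep, pid, day,
                                    seed = derive_seed(cfg$seed, p, day, 7))
      for (m in names(streams))
        write_stream(streams[[m]],
                     file.path(dir, sprintf("%s_day%d_%s.csv", pid, day, m)))
    }
  }
  invisible(dir)
}
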