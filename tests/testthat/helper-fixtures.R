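# shared fixtures built in code

# a small heart-rate window object without going through stream extraction
make_window <- function(samples, fs, modality = "hr", t_center = 1000,
                        duration = 360) {
  n <- if (is.matrix(samples)) nrow(samples) else length(samples)
  structure(
    list(survey_id = "S1", patient_id = "P01", modality = modality,
         t_center = t_center, duration = duration, sampling_rate = fs,
         times = t_center - duration / 2 + (seq_len(n) - 1) / fs,
         samples = samples, n_slots = n,
         n_missing = sum(is.na(if (is.matrix(samples)) samples[, 1] else samples)),
         quality_verdict = "kept", drop_reason = NA_character_),
    class = "feature_window")
}

# forward-generate a noiseless electrodermal trace from a known tonic and
# planted driver impulses, using the same truncated kernel as the generator
forward_eda <- function(n, fs, kernel, tonic, impulse_idx, impulse_amp) {
  driver <- numeric(n)
  driver[impulse_idx] <- impulse_amp
  h <- c(0, kernel$values)
  nfft <- stats::nextn(n + length(h), 2)
  ph <- Re(stats::fft(stats::fft(c(driver, numeric(nfft - n))) *
                        stats::fft(c(h, numeric(nfft - length(h)))),
                      inverse = TRUE)) / nfft
  tonic + ph[seq_len(n)]
}

# simulate a random-intercept logistic data set for GLMM tests
sim_glmm_data <- function(m, nper, beta_feature, sigma_u, intercept = -1,
                          time_effects = c(0, 0.2, 0.3, 0.5)) {
  pid <- rep(seq_len(m), each = nper)
  x <- stats::rnorm(m * nper)
  tg <- sample(1:4, m * nper, replace = TRUE)
  u <- stats::rnorm(m, 0, sigma_u)
  eta <- intercept + beta_feature * x + time_effects[tg] + u[pid]
  y <- stats::rbinom(m * nper, 1, stats::plogis(eta))
  X <- cbind(1, x, tg == 2, tg == 3, tg == 4)
  colnames(X) <- c("(Intercept)", "feature", "tg2", "tg3", "tg4")
  list(y = y, X = X, pid = pid, x = x, tg = tg)
}
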