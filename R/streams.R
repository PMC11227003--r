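#' Construct a sensor stream
#'
#' A \code{sensor_stream} is a uniformly sampled single- or tri-channel time
#' series for one patient and one modality, with explicit missingness
#' (\code{NA} values, never silently dropped rows).  Timestamps are seconds
#' since local midnight of the first study day, so clock time of day is
#' \code{t %% 86400}.
#'
#' @param patient_id character or integer patient identifier.
#' @param modality one of \code{"acc"}, \code{"hr"}, \code{"eda"},
#'   \code{"st"}, \code{"ambient"}.
#' @param sampling_rate sampling rate in Hz.  Conventional rates are 32 (acc),
#'   0.5 (hr), 256 or 8 (eda), 1 (st, ambient).
#' @param t0 timestamp of the first sample, seconds since midnight of day 1.
#' @param values numeric vector (single-channel) or 3-column matrix (acc).
#'   \code{NA} marks a missing sample.
#' @return an object of class \code{sensor_stream}.
#' @export
sensor_stream <- function(patient_id, modality, sampling_rate, t0, values) {
  modality <- match.arg(modality, c("acc", "hr", "eda", "st", "ambient"))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (modality == "acc") {
    values <- as.matrix(values)
    if (ncol(values) != 3L)
      stop("acc streams must have exactly 3 channels (x, y, z)")
  } else {
    if (is.matrix(values) && ncol(values) != 1L)
      stop(sprintf("%s streams must have exactly 1 channel", modality))
    values <- as.numeric(values)
  }
  structure(
    list(patient_id = patient_id, modality = modality,
         sampling_rate = sampling_rate, t0 = as.numeric(t0),
         values = values),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  n <- stream_length(x)
  cat(sprintf("<sensor_stream> patient %s, %s @ %g Hz, %d samples (%.1f s), %.1f%% missing\n",
              x$patient_id, x$modality, x$sampling_rate, n,
              n / x$sampling_rate,
              100 * mean(is.na(stream_values(x)[, 1]))))
  invisible(x)
}

stream_length <- function(stream) {
  if (is.matrix(stream$values)) nrow(stream$values) else length(stream$values)
}

# values as a matrix (1 or 3 columns), for uniform handling
stream_values <- function(stream) {
  if (is.matrix(stream$values)) stream$values else matrix(stream$values, ncol = 1L)
}

stream_times <- function(stream) {
  stream$t0 + (seq_len(stream_length(stream)) - 1L) / stream$sampling_rate
}

#' Write a sensor stream to a columnar text file
#'
#' Dialect: header row, `timestamp_s,value` (or `timestamp_s,x,y,z` for
#' acceleration), missing values as empty fields, UTF-8, "." decimal
#' separator.  Round-trip \code{write_stream} then \code{\link{read_stream}}
#' is lossless including missing markers.
#'
#' @param stream a \code{\link{sensor_stream}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stream <- function(stream, path) {
  v <- stream_values(stream)
  df <- data.frame(timestamp_s = stream_times(stream))
  if (ncol(v) == 3L) {
    df$x <- v[, 1]; df$y <- v[, 2]; df$z <- v[, 3]
  } else {
    df$value <- v[, 1]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a sensor stream from a columnar text file
#'
#' @param path file in the dialect written by \code{\link{write_stream}}.
#' @param modality modality of the stream (determines expected channels).
#' @param patient_id patient identifier to attach (not stored in the file).
#' @param tol tolerance for timestamp non-uniformity, as a fraction of the
#'   sample period (default 1\%).
#' @return a \code{\link{sensor_stream}}.
#' @export
read_stream <- function(path, modality, patient_id = NA_character_, tol = 0.01) {
  modality <- match.arg(modality, c("acc", "hr", "eda", "st", "ambient"))
  df <- utils::read.csv(path, header = TRUE)
  if (!"timestamp_s" %in% names(df))
    stop("malformed stream file: no timestamp_s column")
  value_cols <- setdiff(names(df), "timestamp_s")
  n_chan <- length(value_cols)
  if (modality == "acc" && n_chan != 3L)
    stop(sprintf("acc stream file must have 3 value channels, found %d", n_chan))
  if (modality != "acc" && n_chan != 1L)
    stop(sprintf("%s stream file must have 1 value channel, found %d", modality, n_chan))
  ts <- df$timestamp_s
  if (anyNA(ts)) stop("malformed stream file: missing timestamps")
  if (length(ts) >= 2L) {
    dt <- diff(ts)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    period <- stats::median(dt)
    if (any(abs(dt - period) > tol * period))
      stop("nonuniform timestamps beyond tolerance")
    rate <- 1 / period
  } else {
    rate <- NA_real_
  }
  values <- as.matrix(df[value_cols])
  if (n_chan == 1L) values <- as.numeric(values)
  sensor_stream(patient_id, modality, rate, ts[1], values)
}

#' Extract the 6-minute survey-centered window from a stream
#'
#' Returns all samples with timestamps in the half-open interval
#' \code{[t_center - duration/2, t_center + duration/2)} on the stream's own
#' sample grid.  Slots in the window with no recorded sample (window reaching
#' beyond the recording span) are marked missing, so the proportion missing
#' is well defined for quality control.
#'
#' @param stream a \code{\link{sensor_stream}}.
#' @param t_center window center (the survey submission timestamp), seconds.
#' @param duration window length in seconds (default 360 = 6 min).
#' @param survey_id optional identifier carried through to features.
#' @return a \code{feature_window}: list with \code{samples} (vector or
#'   3-column matrix covering every expected slot, \code{NA} = missing),
#'   \code{times}, \code{n_slots}, \code{n_missing}, and metadata.
#' @export
extract_window <- function(stream, t_center, duration = 360, survey_id = NA) {
  fs <- stream$sampling_rate
  n_slots <- as.integer(round(duration * fs))
  t_start <- t_center - duration / 2
  # first slot: first stream grid point >= t_start (grid: t0 + k/fs)
  k0 <- ceiling((t_start - stream$t0) * fs - 1e-9)
  slot_idx <- k0 + seq_len(n_slots) - 1L     # grid indices (0-based)
  times <- stream$t0 + slot_idx / fs
  v <- stream_values(stream)
  n <- nrow(v)
  samples <- matrix(NA_real_, nrow = n_slots, ncol = ncol(v))
  inside <- slot_idx >= 0L & slot_idx < n
  samples[inside, ] <- v[slot_idx[inside] + 1L, , drop = FALSE]
  if (ncol(samples) == 1L) samples <- as.numeric(samples)
  miss <- if (is.matrix(samples)) rowSums(is.na(samples)) > 0 else is.na(samples)
  structure(
    list(survey_id = survey_id, patient_id = stream$patient_id,
         modality = stream$modality, t_center = t_center,
         duration = duration, sampling_rate = fs,
         times = times, samples = samples,
         n_slots = n_slots, n_missing = sum(miss),
         quality_verdict = "kept", drop_reason = NA_character_),
    class = "feature_window")
}

#' @export
print.feature_window <- function(x, ...) {
  cat(sprintf("<feature_window> %s, center %.1f s, %d slots, %d missing, %s\n",
              x$modality, x$t_center, x$n_slots, x$n_missing, x$quality_verdict))
  invisible(x)
}

mark_dropped <- function(window, reason) {
  window$quality_verdict <- "dropped"
  window$drop_reason <- reason
  window
}
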