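#' Extract summary features from a window series
#'
#' Minimal interpretable statistics per 6-minute window: minimum, maximum,
#' median, and sample standard deviation (denominator n-1); for the
#' slow-varying skin temperature additionally the ordinary-least-squares
#' slope of value against time, in degC/min.
#'
#' @param values numeric series (missing samples ignored).
#' @param times sample timestamps in seconds (required for the slope).
#' @param slope if \code{TRUE}, include the OLS slope feature.
#' @return named numeric vector \code{min}, \code{max}, \code{median},
#'   \code{sd} (and \code{slope}).
#' @export
extract_features <- function(values, times = NULL, slope = FALSE) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2L) stop("feature extraction needs at least 2 samples")
  out <- c(min = min(v), max = max(v), median = stats::median(v),
           sd = stats::sd(v))
  if (slope) {
    stopifnot(!is.null(times))
    tt <- times[ok] / 60   # minutes
    if (stats::var(tt) == 0) {
      out["slope"] <- 0
    } else {
      out["slope"] <- stats::cov(tt, v) / stats::var(tt)
    }
  }
  out
}

#' Center and scale feature values within each patient
#'
#' z-scores each feature using the patient's own mean and sample SD over all
#' of that patient's kept windows (agitated and non-agitated pooled), so a
#' model coefficient is a per-within-patient-SD effect size.  If a patient's
#' SD for a feature is zero (or the patient has fewer than 2 values), the
#' standardized value is set missing and those rows are excluded downstream.
#'
#' @param features data.frame with at least \code{patient_id},
#'   \code{signal}, \code{feature}, \code{value} columns (long format).
#' @return the data.frame with an added \code{z} column.
#' @export
standardize_within_patient <- function(features) {
  stopifnot(all(c("patient_id", "signal", "feature", "value") %in% names(features)))
  key <- interaction(features$patient_id, features$signal, features$feature,
                     drop = TRUE)
  mu <- ave(features$value, key, FUN = function(v) mean(v, na.rm = TRUE))
  sdv <- ave(features$value, key, FUN = function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v)
  })
  z <- (features$value - mu) / sdv
  z[!is.na(sdv) & sdv == 0] <- NA_real_
  features$z <- z
  features
}
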