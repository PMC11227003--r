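#' Quality-control rule set
#'
#' Modality-specific preprocessing thresholds, with the study defaults:
#' heart-rate gaps shorter than 10 s filled by a rolling 10 s median and the
#' rest by cubic spline; windows with >= 50\% missing heart-rate samples
#' dropped; skin temperature valid in the closed range 20-40 degC and
#' windows with <= 50\% valid samples dropped.
#'
#' @param hr_roll_median_s rolling median window for heart-rate gap filling, s.
#' @param hr_spline_order spline order for remaining interior gaps (3 = cubic).
#' @param missing_drop_fraction heart-rate windows with at least this
#'   pre-imputation missing fraction are dropped.
#' @param st_min,st_max valid skin-temperature range, degC (inclusive).
#' @param st_valid_min_fraction skin-temperature windows with valid fraction
#'   less than or equal to this are dropped.
#' @param eda_quality_threshold electrodermal windows with quality indicator
#'   strictly below this are dropped.
#' @return a \code{qc_rules} list.
#' @export
qc_rules <- function(hr_roll_median_s = 10,
                     hr_spline_order = 3,
                     missing_drop_fraction = 0.5,
                     st_min = 20, st_max = 40,
                     st_valid_min_fraction = 0.5,
                     eda_quality_threshold = 0.5) {
  stopifnot(missing_drop_fraction > 0, missing_drop_fraction <= 1,
            st_valid_min_fraction > 0, st_valid_min_fraction <= 1,
            st_min < st_max, hr_roll_median_s > 0)
  structure(as.list(environment()), class = "qc_rules")
}

#' Acceleration magnitude
#'
#' Euclidean norm of the tri-axial acceleration, \eqn{\sqrt{x^2+y^2+z^2}},
#' in g.  Accepts vectors (element-wise) or a 3-column matrix.
#'
#' @param x,y,z per-axis acceleration in g, or \code{x} a 3-column matrix.
#' @return nonnegative magnitude, same length as the inputs.
#' @export
acc_magnitude <- function(x, y = NULL, z = NULL) {
  if (is.matrix(x) && is.null(y)) {
    stopifnot(ncol(x) == 3L)
    y <- x[, 2]; z <- x[, 3]; x <- x[, 1]
  }
  if (any(!is.finite(x) & !is.na(x)) || any(!is.finite(y) & !is.na(y)) ||
      any(!is.finite(z) & !is.na(z)))
    stop("non-finite acceleration input")
  sqrt(x^2 + y^2 + z^2)
}

#' Impute missing heart-rate samples in a window
#'
#' Two-stage gap filling on the 0.5 Hz heart-rate series: gaps strictly
#' shorter than the rolling-median length (10 s) are filled with the
#' centered 10 s rolling median of originally valid neighbors; remaining
#' interior gaps are filled by cubic spline interpolation through the valid
#' samples.  Leading and trailing gaps have no surrounding data and stay
#' missing (no extrapolation).  Valid samples are never altered.
#'
#' @param window a heart-rate \code{feature_window} from
#'   \code{\link{extract_window}}.
#' @param rules a \code{\link{qc_rules}}.
#' @return the window with \code{samples} imputed, plus counts
#'   \code{n_imputed_median}, \code{n_imputed_spline}, \code{n_unfilled}.
#' @export
impute_hr_window <- function(window, rules = qc_rules()) {
  x <- window$samples
  fs <- window$sampling_rate
  valid0 <- !is.na(x)
  n <- length(x)
  out <- x
  half <- floor(rules$hr_roll_median_s * fs / 2)   # samples each side
  max_gap <- rules$hr_roll_median_s * fs           # gap must be < this many samples

  # identify missing runs
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_med <- 0L
  for (k in which(r$values)) {
    if (r$lengths[k] >= max_gap) next
    for (i in starts[k]:ends[k]) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      nb <- x[lo:hi][valid0[lo:hi]]
      if (length(nb) > 0) {
        out[i] <- stats::median(nb)
        n_med <- n_med + 1L
      }
    }
  }
  # cubic spline through valid samples for remaining interior gaps
  still <- is.na(out)
  n_spl <- 0L
  if (any(still) && sum(valid0) >= 4L) {
    idx_valid <- which(valid0)
    interior <- which(still)
    interior <- interior[interior > min(idx_valid) & interior < max(idx_valid)]
    if (length(interior) > 0) {
      sf <- stats::splinefun(idx_valid, x[idx_valid], method = "fmm")
      out[interior] <- sf(interior)
      n_spl <- length(interior)
    }
  }
  window$samples <- out
  window$n_imputed_median <- n_med
  window$n_imputed_spline <- n_spl
  window$n_unfilled <- sum(is.na(out))
  window$missing_fraction_pre <- mean(!valid0)
  window
}

#' Heart-rate window quality verdict
#'
#' A window is dropped when the proportion of missing samples (the number
#' of values that would need imputing, i.e. assessed before imputation) is
#' at least \code{missing_drop_fraction} (default 50\%).
#'
#' @param window a heart-rate \code{feature_window} (imputed or not; the
#'   verdict uses pre-imputation missingness).
#' @param rules a \code{\link{qc_rules}}.
#' @return \code{"kept"} or \code{"dropped"}.
#' @export
hr_window_verdict <- function(window, rules = qc_rules()) {
  frac <- if (!is.null(window$missing_fraction_pre)) window$missing_fraction_pre
          else mean(is.na(window$samples))
  if (frac >= rules$missing_drop_fraction) "dropped" else "kept"
}

#' Skin-temperature window quality verdict
#'
#' A sample is valid when present and inside the closed range
#' [\code{st_min}, \code{st_max}] degC.  The window is dropped when the
#' valid fraction is less than or equal to \code{st_valid_min_fraction}.
#'
#' @param window a skin-temperature \code{feature_window}.
#' @param rules a \code{\link{qc_rules}}.
#' @return \code{"kept"} or \code{"dropped"}.
#' @export
st_window_verdict <- function(window, rules = qc_rules()) {
  x <- window$samples
  valid <- !is.na(x) & x >= rules$st_min & x <= rules$st_max
  if (mean(valid) <= rules$st_valid_min_fraction) "dropped" else "kept"
}

#' Mask invalid skin-temperature samples
#'
#' Out-of-range samples are excluded from feature computation (they are
#' sensor artifacts, not physiology).
#'
#' @param window a skin-temperature \code{feature_window}.
#' @param rules a \code{\link{qc_rules}}.
#' @return the window with out-of-range samples set missing.
#' @export
st_mask_invalid <- function(window, rules = qc_rules()) {
  x <- window$samples
  x[!is.na(x) & (x < rules$st_min | x > rules$st_max)] <- NA_real_
  window$samples <- x
  window
}

#' Accelerometer window magnitude series
#'
#' Per-sample acceleration magnitude for a tri-axial window.  No quality
#' threshold is applied to acceleration; only a fully empty window is
#' dropped (reason \code{"no_data"}).
#'
#' @param window an acceleration \code{feature_window} (3-channel samples).
#' @return the window with \code{samples} replaced by the magnitude series
#'   and a quality verdict.
#' @export
acc_window_series <- function(window) {
  v <- window$samples
  stopifnot(is.matrix(v), ncol(v) == 3L)
  mag <- acc_magnitude(v)
  window$samples <- mag
  if (all(is.na(mag))) window <- mark_dropped(window, "no_data")
  window
}
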