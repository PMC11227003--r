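#' Bateman impulse-response kernel
#'
#' Difference-of-exponentials impulse response
#' \eqn{h(t) = e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}}, normalized to unit
#' peak, used to model a single skin conductance response.  The kernel is
#' discretized on the analysis grid starting at lag one sample (its value at
#' lag 0 is 0), so a unit driver impulse at sample \eqn{j} contributes
#' \eqn{h[k]} to samples \eqn{j+k}.
#'
#' @param tau_rise,tau_decay time constants in seconds,
#'   \code{0 < tau_rise < tau_decay}.
#' @param fs sampling rate of the analysis grid, Hz.
#' @param length_s kernel support; default 12 decay constants (truncation
#'   below 1e-5 of the peak).
#' @return list with \code{values} (kernel at lags 1..L samples),
#'   \code{tau_rise}, \code{tau_decay}, \code{fs}, \code{peak} (the
#'   pre-normalization peak value, needed for exact inversion).
#' @export
bateman_kernel <- function(tau_rise = 0.75, tau_decay = 2.0, fs = 8,
                           length_s = 12 * tau_decay) {
  stopifnot(tau_rise > 0, tau_rise < tau_decay)
  L <- max(4L, ceiling(length_s * fs))
  k <- seq_len(L)
  h <- exp(-k / (fs * tau_decay)) - exp(-k / (fs * tau_rise))
  peak <- max(h)
  structure(list(values = h / peak, tau_rise = tau_rise,
                 tau_decay = tau_decay, fs = fs, peak = peak),
            class = "bateman_kernel")
}

#' Savitzky-Golay filter and downsample a raw electrodermal series
#'
#' Mitigates ADC quantization noise in the raw 256 Hz skin-conductance
#' signal with a Savitzky-Golay polynomial filter (order 2, 1 s window by
#' default; preserves constants and linear trends, and SCR rise times of
#' ~1 s) and then decimates to the 8 Hz analysis rate by taking every
#' \code{fs_in/fs_out}-th sample.
#'
#' @param raw numeric series at \code{fs_in} Hz.
#' @param fs_in,fs_out input and output sampling rates (ratio must be an
#'   integer).
#' @param order polynomial order of the filter.
#' @param window_s filter window length in seconds (forced odd in samples).
#' @return numeric series at \code{fs_out} Hz.
#' @export
filter_and_downsample <- function(raw, fs_in = 256, fs_out = 8,
                                  order = 2, window_s = 1) {
  n_filt <- round(window_s * fs_in)
  if (n_filt %% 2 == 0) n_filt <- n_filt + 1
  if (length(raw) < n_filt)
    stop("input shorter than the Savitzky-Golay filter window")
  dec <- fs_in / fs_out
  if (abs(dec - round(dec)) > 1e-9) stop("fs_in must be an integer multiple of fs_out")
  sm <- signal::sgolayfilt(raw, p = order, n = n_filt)
  sm[seq(1, length(sm), by = round(dec))]
}

# per-5-s-segment cleanliness on the 8 Hz signal; returns logical vector,
# one element per segment (TRUE = clean)
eda_segment_clean <- function(x, fs = 8, seg_s = 5,
                              range_min = 0.05, range_max = 60,
                              max_slope = 10, flat_range = 0.001) {
  seg_len <- round(seg_s * fs)
  n_seg <- floor(length(x) / seg_len)
  if (n_seg == 0L) return(logical(0))
  vapply(seq_len(n_seg), function(i) {
    s <- x[((i - 1) * seg_len + 1):(i * seg_len)]
    if (anyNA(s)) return(FALSE)
    if (any(s < range_min | s > range_max)) return(FALSE)
    if (max(abs(diff(s))) * fs > max_slope) return(FALSE)
    if (diff(range(s)) < flat_range) return(FALSE)   # flat for the whole 5 s
    TRUE
  }, logical(1))
}

#' Rule-based electrodermal quality indicator
#'
#' Fraction of 5 s segments of the filtered 8 Hz signal that are clean.  A
#' segment is unclean if it contains missing samples, any sample outside
#' the physiological range (0.05-60 uS), a sample-to-sample slope exceeding
#' 10 uS/s (motion/electrode artifact), or is flat (range < 0.001 uS over
#' the full 5 s, indicating a disconnected or railed sensor).  Windows with
#' an indicator below 0.5 are subsequently removed, the same decision
#' threshold used with model-based quality scores.
#'
#' @param filtered 8 Hz electrodermal series, uS.
#' @param fs sampling rate (8 Hz).
#' @return quality indicator in [0, 1].
#' @export
quality_indicator <- function(filtered, fs = 8) {
  clean <- eda_segment_clean(filtered, fs = fs)
  if (length(clean) == 0L) return(0)
  mean(clean)
}

#' Electrodermal window verdict
#'
#' @param quality quality indicator from \code{\link{quality_indicator}}.
#' @param rules a \code{\link{qc_rules}} (threshold 0.5 by default; strictly
#'   below the threshold is dropped).
#' @return \code{"kept"} or \code{"dropped"}.
#' @export
eda_window_verdict <- function(quality, rules = qc_rules()) {
  if (quality < rules$eda_quality_threshold) "dropped" else "kept"
}

#' Interpolate artifact segments in an electrodermal window
#'
#' Samples in unclean segments are replaced by cubic interpolation through
#' the clean samples; unclean stretches at the window edges (no clean data
#' on one side) are held at the nearest clean value.
#'
#' @param filtered 8 Hz electrodermal series.
#' @param clean_mask per-segment logical from the quality rules (or a
#'   per-sample logical of the same length as \code{filtered}); \code{NULL}
#'   recomputes it from the quality rules.
#' @param fs sampling rate.
#' @param seg_s segment length in seconds.
#' @return cleaned series of the same length.
#' @export
interpolate_artifacts <- function(filtered, clean_mask = NULL, fs = 8, seg_s = 5) {
  n <- length(filtered)
  if (is.null(clean_mask)) clean_mask <- eda_segment_clean(filtered, fs, seg_s)
  if (length(clean_mask) == n) {
    sample_clean <- clean_mask
  } else {
    seg_len <- round(seg_s * fs)
    sample_clean <- rep(FALSE, n)
    for (i in seq_along(clean_mask))
      if (clean_mask[i])
        sample_clean[((i - 1) * seg_len + 1):(i * seg_len)] <- TRUE
    # trailing partial segment follows the verdict of the last full segment
    if (n > length(clean_mask) * seg_len && length(clean_mask) > 0)
      sample_clean[(length(clean_mask) * seg_len + 1):n] <-
        clean_mask[length(clean_mask)]
  }
  sample_clean <- sample_clean & !is.na(filtered)
  if (all(sample_clean)) return(filtered)
  if (!any(sample_clean)) return(filtered)
  out <- filtered
  idx <- which(sample_clean)
  bad <- which(!sample_clean)
  interior <- bad[bad > min(idx) & bad < max(idx)]
  if (length(interior) > 0 && length(idx) >= 4L) {
    sf <- stats::splinefun(idx, filtered[idx], method = "fmm")
    out[interior] <- sf(interior)
  } else if (length(interior) > 0) {
    out[interior] <- stats::approx(idx, filtered[idx], xout = interior,
                                   rule = 2)$y
  }
  out[bad[bad < min(idx)]] <- filtered[min(idx)]
  out[bad[bad > max(idx)]] <- filtered[max(idx)]
  out
}

# exact discrete inverse of the (truncated) Bateman kernel:
# if p[t] = sum_k h[k] d[t-k] with h[k] = (a^k - b^k)/peak, then
# d[t] = peak/(a-b) * (p[t+1] - (a+b) p[t] + a b p[t-1])
bateman_inverse <- function(p, kernel) {
  fs <- kernel$fs
  a <- exp(-1 / (fs * kernel$tau_decay))
  b <- exp(-1 / (fs * kernel$tau_rise))
  n <- length(p)
  d <- numeric(n)
  pm1 <- c(0, p[-n])
  pp1 <- c(p[-1], 0)
  d <- kernel$peak / (a - b) * (pp1 - (a + b) * p + a * b * pm1)
  d
}

# The discretized Bateman kernel h[k] = (a^k - b^k)/peak (a, b the per-sample
# decay/rise factors) is a 2-pole IIR system
#   H(z) = c z^-1 / ((1 - a z^-1)(1 - b z^-1)),  c = (a - b)/peak,
# so convolution with it and with its adjoint are O(n) recursive filters.
bateman_poles <- function(kernel) {
  fs <- kernel$fs
  list(a = exp(-1 / (fs * kernel$tau_decay)),
       b = exp(-1 / (fs * kernel$tau_rise)))
}

bateman_conv <- function(d, kernel) {
  p <- bateman_poles(kernel)
  cc <- (p$a - p$b) / kernel$peak
  x <- cc * c(0, d[-length(d)])
  as.numeric(stats::filter(x, c(p$a + p$b, -p$a * p$b), method = "recursive"))
}

bateman_conv_adjoint <- function(v, kernel) {
  rev(bateman_conv(rev(v), kernel))
}

# nonnegative ridge least squares  min 0.5||r - K d||^2 + 0.5 ridge ||d||^2
# by projected FISTA warm-started from the clipped exact kernel inverse;
# on noiseless forward-model data the warm start is already the solution.
nnls_deconvolve <- function(r, kernel, ridge = 1e-6, max_iter = 50,
                            tol = 1e-6, warm = NULL) {
  p <- bateman_poles(kernel)
  if (is.null(warm)) warm <- pmax(0, bateman_inverse(r, kernel))
  .nnls_bateman_cpp(r, p$a, p$b, kernel$peak, ridge, as.integer(max_iter),
                    tol, warm)
}

#' Precompute the coarse tonic spline basis
#'
#' @param n series length in samples.
#' @param fs sampling rate, Hz.
#' @param knot_spacing_s spacing of the tonic spline knots, s.
#' @return list with the B-spline basis matrix and its QR decomposition.
#' @export
tonic_basis <- function(n, fs = 8, knot_spacing_s = 30) {
  n_knots <- max(1L, floor((n / fs) / knot_spacing_s) - 1L)
  knots <- if (n_knots > 0) seq(1, n, length.out = n_knots + 2L)[-c(1, n_knots + 2L)]
           else NULL
  B <- splines::bs(seq_len(n), knots = knots, degree = 3, intercept = TRUE)
  list(B = B, qr = qr(B), n = n)
}

#' Decompose a cleaned electrodermal window into tonic and phasic components
#'
#' Deconvolution-based decomposition: the tonic (skin conductance level) is
#' a slowly varying baseline represented on a coarse cubic spline basis and
#' initialized through the troughs of the signal (per-10 s-segment minima);
#' the phasic component is a nonnegative driver convolved with the Bateman
#' kernel, estimated by nonnegative ridge least squares on the residual.
#' Two alternating refits of tonic and driver tighten the reconstruction.
#'
#' @param cleaned artifact-free 8 Hz series, uS.
#' @param kernel a \code{\link{bateman_kernel}} at the same sampling rate.
#' @param knot_spacing_s spacing of the tonic spline knots, s.
#' @param trough_seg_s segment length for trough initialization, s.
#' @param ridge ridge penalty on the driver.
#' @param max_iter,tol solver controls for the nonnegative least squares
#'   (\code{max_iter} is the total iteration budget across passes).
#' @param n_alternations tonic/driver refit passes after initialization.
#' @param basis optional precomputed \code{tonic_basis()} (cache it when
#'   decomposing many windows of equal length).
#' @return list with \code{tonic}, \code{phasic}, \code{driver} (all the
#'   length of \code{cleaned}), \code{residual_rmse}, \code{converged},
#'   \code{tonic_max_abs_slope} (uS/s).
#' @export
eda_decompose <- function(cleaned, kernel = bateman_kernel(),
                          knot_spacing_s = 30, trough_seg_s = 10,
                          ridge = 1e-6, max_iter = 30, tol = 1e-6,
                          n_alternations = 1, basis = NULL) {
  stopifnot(all(is.finite(cleaned)))
  fs <- kernel$fs
  n <- length(cleaned)
  # coarse cubic B-spline basis for the tonic (cacheable across windows)
  if (is.null(basis) || basis$n != n) basis <- tonic_basis(n, fs, knot_spacing_s)
  B <- basis$B
  tonic_fit <- function(target) {
    cf <- qr.coef(basis$qr, target)
    cf[is.na(cf)] <- 0
    as.numeric(B %*% cf)
  }
  # trough initialization: per-segment minima
  seg_len <- max(2L, round(trough_seg_s * fs))
  n_seg <- max(1L, floor(n / seg_len))
  mins_idx <- vapply(seq_len(n_seg), function(i) {
    lo <- (i - 1L) * seg_len + 1L
    hi <- if (i == n_seg) n else i * seg_len
    as.integer(lo - 1L + which.min(cleaned[lo:hi]))
  }, integer(1))
  fit0 <- stats::lm.fit(B[mins_idx, , drop = FALSE], cleaned[mins_idx])
  coef0 <- fit0$coefficients
  coef0[is.na(coef0)] <- 0
  tonic <- as.numeric(B %*% coef0)
  it_each <- max(10L, ceiling(max_iter / (n_alternations + 1L)))
  sol <- nnls_deconvolve(cleaned - tonic, kernel, ridge, it_each, tol)
  for (pass in seq_len(n_alternations)) {
    # refit tonic on the signal minus the current phasic estimate
    tonic <- tonic_fit(cleaned - sol$phasic)
    sol <- nnls_deconvolve(cleaned - tonic, kernel, ridge, it_each, tol,
                           warm = sol$driver)
  }
  tonic <- tonic_fit(cleaned - sol$phasic)   # final free refit
  resid <- cleaned - tonic - sol$phasic
  if (!sol$converged && sqrt(mean(resid^2)) > 0.1)
    warning("nonnegative deconvolution did not reach tolerance (residual RMSE ",
            signif(sqrt(mean(resid^2)), 3), " uS)")
  list(tonic = tonic, phasic = sol$phasic, driver = sol$driver,
       residual_rmse = sqrt(mean(resid^2)), converged = sol$converged,
       tonic_max_abs_slope = if (n > 1) max(abs(diff(tonic))) * fs else 0)
}

#' Locate discrete impulses in a recovered driver
#'
#' Clusters contiguous driver mass (separated by gaps of at least
#' \code{min_gap_s}) into impulses with a mass-weighted time and a total
#' amplitude, for comparing recovered SCR events against planted ones.
#'
#' @param driver nonnegative driver series from \code{\link{eda_decompose}}.
#' @param fs sampling rate, Hz.
#' @param threshold driver values at or below this are treated as zero.
#' @param min_gap_s minimum gap separating two impulses, s.
#' @return data.frame with columns \code{time_s} (relative to the start of
#'   the series) and \code{amplitude}.
#' @export
scr_peaks <- function(driver, fs = 8, threshold = 1e-3, min_gap_s = 1) {
  on <- driver > threshold
  if (!any(on)) return(data.frame(time_s = numeric(0), amplitude = numeric(0)))
  idx <- which(on)
  gap <- c(Inf, diff(idx))
  cluster <- cumsum(gap >= min_gap_s * fs)
  times <- tapply(idx, cluster, function(i)
    sum((i - 1) / fs * driver[i]) / sum(driver[i]))
  amps <- tapply(idx, cluster, function(i) sum(driver[i]))
  data.frame(time_s = as.numeric(times), amplitude = as.numeric(amps))
}

#' Preprocess one electrodermal window end to end
#'
#' Applies the full electrodermal branch: Savitzky-Golay filtering and
#' decimation (if the window is at 256 Hz), the rule-based quality
#' indicator and 0.5 keep/drop threshold, artifact interpolation, and
#' tonic/phasic decomposition.
#'
#' @param window an electrodermal \code{feature_window} at 256 or 8 Hz.
#' @param rules a \code{\link{qc_rules}}.
#' @param kernel a \code{\link{bateman_kernel}} at 8 Hz.
#' @param basis optional precomputed \code{\link{tonic_basis}}.
#' @return the window with added fields \code{quality}, \code{cleaned},
#'   \code{tonic}, \code{phasic}, \code{driver}, and its quality verdict
#'   set; dropped windows skip decomposition.
#' @export
preprocess_eda_window <- function(window, rules = qc_rules(),
                                  kernel = bateman_kernel(), basis = NULL) {
  x <- window$samples
  fs <- window$sampling_rate
  if (all(is.na(x))) return(mark_dropped(window, "no_data"))
  if (fs > 8) {
    if (anyNA(x)) {   # filter needs contiguous data; missing slots stay unclean
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      x8 <- filter_and_downsample(x, fs_in = fs, fs_out = 8)
      na8 <- is.na(window$samples[seq(1, length(window$samples), by = round(fs / 8))])
      x8[na8[seq_along(x8)]] <- NA_real_
    } else {
      x8 <- filter_and_downsample(x, fs_in = fs, fs_out = 8)
    }
    fs <- 8
  } else {
    x8 <- x
  }
  clean_mask <- eda_segment_clean(x8, fs = fs)
  q <- if (length(clean_mask)) mean(clean_mask) else 0
  window$quality <- q
  window$samples_8hz <- x8
  verdict <- eda_window_verdict(q, rules)
  if (verdict == "dropped") return(mark_dropped(window, "low_quality"))
  cleaned <- interpolate_artifacts(x8, clean_mask, fs = fs)
  if (anyNA(cleaned)) cleaned[is.na(cleaned)] <- stats::median(cleaned, na.rm = TRUE)
  dec <- eda_decompose(cleaned, kernel, basis = basis)
  window$cleaned <- cleaned
  window$tonic <- dec$tonic
  window$phasic <- dec$phasic
  window$driver <- dec$driver
  window$decomposition_rmse <- dec$residual_rmse
  window
}
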