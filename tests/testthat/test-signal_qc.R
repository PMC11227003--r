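test_that("acceleration magnitude is the Euclidean norm", {
  expect_equal(acc_magnitude(1, 0, 0), 1.0)
  expect_equal(acc_magnitude(0.6, 0.8, 0), 1.0)
  expect_equal(acc_magnitude(1, 2, 2), 3.0)
  expect_equal(acc_magnitude(cbind(c(1, 0.6), c(0, 0.8), c(0, 0))), c(1, 1))
  expect_error(acc_magnitude(Inf, 0, 0), "non-finite")
})

test_that("accelerometer windows keep any data; only empty windows drop", {
  rest <- make_window(cbind(0, 0, rep(1, 100)), fs = 32, modality = "acc")
  w <- acc_window_series(rest)
  expect_equal(w$samples, rep(1, 100))
  expect_equal(w$quality_verdict, "kept")

  shake <- make_window(cbind(rep(c(0.5, 0), 50), 0, 1), fs = 32,
                       modality = "acc")
  ws <- acc_window_series(shake)
  expect_gt(sd(ws$samples), 0)

  empty <- make_window(matrix(NA_real_, 100, 3), fs = 32, modality = "acc")
  expect_equal(acc_window_series(empty)$quality_verdict, "dropped")
  expect_equal(acc_window_series(empty)$drop_reason, "no_data")
})

test_that("short heart-rate gaps are filled with the rolling 10 s median", {
  # 0.5 Hz: the centered 10 s window spans two samples on each side
  x <- c(80, 82, 84, NA, 86, 88, 90)
  w <- make_window(x, fs = 0.5)
  out <- impute_hr_window(w)
  # valid neighbors within +-2 samples of the gap: 82, 84, 86, 88
  expect_equal(out$samples[4], median(c(82, 84, 86, 88)))
  expect_equal(out$samples[-4], x[-4])   # valid samples untouched
  expect_equal(out$n_imputed_median, 1L)
})

test_that("longer interior gaps are spline-interpolated, exact on a cubic", {
  fs <- 0.5
  tt <- seq_len(60)
  cubic <- 70 + 0.5 * tt - 0.02 * tt^2 + 0.0005 * tt^3
  x <- cubic
  gap <- 25:30          # 6 samples = 12 s >= the 10 s rolling window
  x[gap] <- NA
  out <- impute_hr_window(make_window(x, fs = fs))
  expect_equal(out$samples[gap], cubic[gap], tolerance = 1e-8)
  expect_equal(out$n_imputed_spline, length(gap))
})

test_that("leading and trailing gaps stay missing (no extrapolation)", {
  x <- c(rep(NA_real_, 8), 70 + rnorm(40), rep(NA_real_, 10))
  out <- impute_hr_window(make_window(x, fs = 0.5))
  expect_true(all(is.na(out$samples[1:8])))
  expect_true(all(is.na(out$samples[49:58])))
  expect_false(anyNA(out$samples[9:48]))
})

test_that("heart-rate drop rule uses pre-imputation missingness at >= 50%", {
  mk <- function(n_miss) {
    x <- rnorm(180, 70, 3)
    if (n_miss > 0) x[seq_len(n_miss)] <- NA
    impute_hr_window(make_window(x, fs = 0.5))
  }
  expect_equal(hr_window_verdict(mk(90)), "dropped")   # exactly 50%
  expect_equal(hr_window_verdict(mk(89)), "kept")
  expect_equal(hr_window_verdict(mk(0)), "kept")
})

test_that("skin-temperature windows drop at <= 50% valid; 20-40 degC closed range", {
  mk <- function(n_valid, fill = 33) {
    x <- rep(NA_real_, 360)
    if (n_valid > 0) x[seq_len(n_valid)] <- fill
    make_window(x, fs = 1, modality = "st")
  }
  expect_equal(st_window_verdict(mk(180)), "dropped")  # exactly 50%
  expect_equal(st_window_verdict(mk(181)), "kept")

  # out-of-range counts as invalid; the boundaries themselves are valid
  x <- rep(33, 360); x[1:180] <- 41
  expect_equal(st_window_verdict(make_window(x, 1, "st")), "dropped")
  x2 <- c(rep(20, 181), rep(40, 100), rep(45, 79))
  expect_equal(st_window_verdict(make_window(x2, 1, "st")), "kept")

  masked <- st_mask_invalid(make_window(c(19.99, 20, 33, 40, 40.01), 1, "st"))
  expect_equal(is.na(masked$samples), c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("imputation accounting is consistent and verdicts are monotone", {
  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(180, 70, 3)
    n_miss <- sample(0:120, 1)
    miss <- sample(180, n_miss)
    x[miss] <- NA
    w <- impute_hr_window(make_window(x, fs = 0.5))
    n_filled <- w$n_imputed_median + w$n_imputed_spline
    expect_equal(n_filled + w$n_unfilled, n_miss)
    expect_equal(w$samples[setdiff(seq_len(180), miss)],
                 x[setdiff(seq_len(180), miss)])
    # removing additional valid samples can only push toward dropping
    v1 <- hr_window_verdict(w)
    x2 <- x
    x2[sample(which(!is.na(x)), 30)] <- NA
    v2 <- hr_window_verdict(impute_hr_window(make_window(x2, fs = 0.5)))
    if (v1 == "dropped") expect_equal(v2, "dropped")
  }
})
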