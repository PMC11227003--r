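test_that("Savitzky-Golay filter preserves constants and linear ramps", {
  const <- rep(2, 256 * 10)
  out <- filter_and_downsample(const)
  expect_equal(out, rep(2, 80), tolerance = 1e-10)

  ramp <- seq(1, 3, length.out = 256 * 10)
  outr <- filter_and_downsample(ramp)
  inner <- 5:76   # away from the filter edges
  expect_equal(outr[inner], ramp[seq(1, length(ramp), by = 32)][inner],
               tolerance = 1e-8)

  # 360 s at 256 Hz decimates to 2880 samples at 8 Hz
  expect_length(filter_and_downsample(rnorm(256 * 360, 2, 0.1)), 2880)
  expect_error(filter_and_downsample(rnorm(100)), "shorter")
})

test_that("quality indicator applies the range/slope/flat segment rules", {
  set.seed(3)
  fs <- 8
  clean <- 2 + 0.1 * sin(seq_len(360 * fs) / 40) + rnorm(360 * fs, 0, 0.02)
  expect_equal(quality_indicator(clean), 1.0)

  expect_equal(quality_indicator(rep(0, 360 * fs)), 0.0)

  # half the window railed at 80 uS -> quality 0.5
  half <- clean
  half[seq_len(180 * fs)] <- 80
  expect_equal(quality_indicator(half), 0.5)

  # quality is invariant to an in-range constant offset
  expect_equal(quality_indicator(clean + 5), quality_indicator(clean))

  # a single large jump makes that segment unclean
  jump <- clean
  jump[1000] <- jump[1000] + 5    # 40 uS/s slope at 8 Hz
  expect_equal(quality_indicator(jump), 1 - 1 / 72)
})

test_that("artifact interpolation restores a linear trend and handles edges", {
  fs <- 8
  n <- 360 * fs
  lin <- seq(2, 4, length.out = n)
  x <- lin
  seg <- 41:80                  # one 5 s artifact segment (segment 2)
  x[seg] <- 80
  mask <- agitsense:::eda_segment_clean(x, fs)
  expect_false(mask[2])
  out <- interpolate_artifacts(x, mask, fs)
  expect_equal(out[seg], lin[seg], tolerance = 1e-6)

  # no artifacts: identity
  expect_identical(interpolate_artifacts(lin, rep(TRUE, 72), fs), lin)

  # artifact at the window start is held at the first clean value
  x2 <- lin; x2[1:40] <- 0
  out2 <- interpolate_artifacts(x2, agitsense:::eda_segment_clean(x2, fs), fs)
  expect_equal(out2[1:40], rep(lin[41], 40))
})

test_that("electrodermal verdict threshold is strict at 0.5", {
  expect_equal(eda_window_verdict(0.5), "kept")
  expect_equal(eda_window_verdict(0.49), "dropped")
  expect_equal(eda_window_verdict(1.0), "kept")
})

test_that("decomposition of a constant gives pure tonic, zero phasic/driver", {
  dec <- eda_decompose(rep(2, 2880), bateman_kernel())
  expect_equal(dec$tonic, rep(2, 2880), tolerance = 1e-8)
  expect_lt(max(abs(dec$phasic)), 1e-8)
  expect_lt(max(dec$driver), 1e-8)
})

test_that("a planted kernel impulse is recovered in time and amplitude", {
  set.seed(9)
  kern <- bateman_kernel()
  n <- 2880
  y <- forward_eda(n, 8, kern, tonic = rep(2, n),
                   impulse_idx = 180 * 8 + 1, impulse_amp = 0.4)
  dec <- eda_decompose(y, kern)
  pk <- scr_peaks(dec$driver, fs = 8, threshold = 0.02)
  main <- pk[which.max(pk$amplitude), ]
  expect_lt(abs(main$time_s - 180), 0.5)
  expect_lt(abs(main$amplitude - 0.4) / 0.4, 0.1)
})

test_that("doubling a planted driver roughly doubles the recovered phasic", {
  set.seed(10)
  kern <- bateman_kernel()
  n <- 2880
  idx <- c(500, 1400, 2300)
  y1 <- forward_eda(n, 8, kern, rep(2, n), idx, c(0.3, 0.3, 0.3))
  y2 <- forward_eda(n, 8, kern, rep(2, n), idx, c(0.6, 0.6, 0.6))
  d1 <- eda_decompose(y1, kern)
  d2 <- eda_decompose(y2, kern)
  ratio <- max(d2$phasic) / max(d1$phasic)
  expect_lt(abs(ratio - 2) / 2, 0.1)
})

test_that("tonic output varies slowly", {
  set.seed(12)
  kern <- bateman_kernel()
  n <- 2880
  tt <- seq(0, by = 1 / 8, length.out = n)
  y <- forward_eda(n, 8, kern, 2 + 0.4 * sin(2 * pi * tt / 240),
                   sample(200:2600, 12), runif(12, 0.2, 0.7))
  dec <- eda_decompose(y, kern)
  expect_lt(dec$tonic_max_abs_slope, 0.1)   # uS/s ceiling
})

test_that("the full electrodermal branch drops nonwear and artifact windows", {
  kern <- bateman_kernel()
  rules <- qc_rules()
  empty <- make_window(rep(NA_real_, 2880), fs = 8, modality = "eda")
  expect_equal(preprocess_eda_window(empty, rules, kern)$quality_verdict,
               "dropped")
  set.seed(4)
  bad <- make_window(c(rep(0, 1500), 2 + rnorm(1380, 0, 0.05)), fs = 8,
                     modality = "eda")
  out <- preprocess_eda_window(bad, rules, kern)
  expect_equal(out$quality_verdict, "dropped")
  expect_equal(out$drop_reason, "low_quality")

  good <- make_window(2 + 0.1 * sin(seq_len(2880) / 50) +
                        rnorm(2880, 0, 0.02), fs = 8, modality = "eda")
  outg <- preprocess_eda_window(good, rules, kern)
  expect_equal(outg$quality_verdict, "kept")
  expect_equal(outg$tonic + outg$phasic, outg$cleaned,
               tolerance = 0.05)
})
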