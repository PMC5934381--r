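fs <- 44100

# segmentation object with known spans, for arithmetic-only checks
manual_seg <- function(pulses) {
  structure(list(
    calls = data.frame(onset = min(pulses$onset), offset = max(pulses$offset)),
    pulses = list(pulses),
    threshold_used = 0.1), class = "call_segmentation")
}

test_that("temporal variables follow their stated definitions", {
  p <- call_parameters(2000, 4, 0.1, 0.1, 80)
  w <- synthesize_call(p, fs)
  pulses <- data.frame(onset = c(0, 0.2, 0.4, 0.6),
                       offset = c(0.1, 0.3, 0.5, 0.7))
  f <- extract_features(w, manual_seg(pulses))
  expect_equal(f$call_duration, 0.7)
  expect_equal(f$n_pulses, 4)
  expect_equal(f$mean_pulse_duration, 0.1)
  expect_equal(f$mean_inter_pulse_interval, 0.1)
  expect_equal(f$pulse_rate, 4 / 0.7)
})

test_that("modulation depth is (max - min) / max of the pulse envelope", {
  # direct check of the formula on a constructed envelope
  env <- c(rep(1.0, 50), rep(0.2, 50), rep(1.0, 50))
  expect_equal(pulse_modulation_depth(env, fs = 1000, onset = 0,
                                      offset = 0.15, edge_exclude = 0),
               80)
  # and through the full path on a synthesized call
  p <- call_parameters(2000, 3, 0.1, 0.1, 80)
  w <- synthesize_call(p, fs)
  seg <- segment_calls(compute_envelope(w), 0.1, 0.005, 0.5)
  f <- extract_features(w, seg)
  expect_equal(f$modulation_depth, 80, tolerance = 0.02)
})

test_that("dominant frequency comes from the central pulse", {
  # 5 pulses; only pulse 3 carries 1500 Hz, the rest 2500 Hz
  p15 <- call_parameters(1500, 1, 0.05, 0, 0)
  p25 <- call_parameters(2500, 1, 0.05, 0, 0)
  pulse15 <- synthesize_pulse(p15, fs)$samples
  pulse25 <- synthesize_pulse(p25, fs)$samples
  gap <- numeric(round(0.05 * fs))
  x <- c(pulse25, gap, pulse25, gap, pulse15, gap, pulse25, gap, pulse25)
  w <- waveform(x, fs)
  seg <- segment_calls(compute_envelope(w), 0.1, 0.005, 0.5)
  expect_equal(nrow(seg$pulses[[1]]), 5)
  f <- extract_features(w, seg)
  expect_lt(abs(f$dominant_frequency - 1500), 44100 / 4096 + 1e-9)
})

test_that("single-pulse calls report a missing inter-pulse interval", {
  p <- call_parameters(2000, 1, 0.1, 0, 40)
  w <- synthesize_call(p, fs)
  seg <- segment_calls(compute_envelope(w), 0.1, 0.005, 0.5)
  f <- extract_features(w, seg)
  expect_true(is.na(f$mean_inter_pulse_interval))
  expect_equal(f$n_pulses, 1)
})

test_that("correction fitting matches its OLS/correlation oracle", {
  x <- 1:5
  m <- fit_correction(2 * x, x)
  expect_equal(m$b, 2.0)
  expect_equal(m$r, 1.0)
  expect_true(m$apply)

  m0 <- fit_correction(rep(3, 5), x)
  expect_equal(m0$b, 0)
  expect_false(m0$apply)

  withr::with_seed(42, {
    xx <- runif(50, 0, 10)
    yy <- 3 * xx + rnorm(50, 0, 0.1)
  })
  mf <- fit_correction(yy, xx)
  expect_gt(mf$b, 2.9)
  expect_lt(mf$b, 3.1)
  expect_equal(mf$b, unname(coef(lm(yy ~ xx))[2]))

  expect_error(fit_correction(1:5, rep(2, 5)), "constant")
  expect_error(fit_correction(1:2, 1:2), "at least 3")
})

test_that("covariate correction follows Ycorr = Y - b*Xmeas + b*Xmean", {
  m <- structure(list(b = 2, x_mean = 3, r = 0.9, p = 0.001,
                      apply = TRUE, alpha = 0.05),
                 class = "correction_model")
  expect_equal(correct_variable(10, m, 3), 10)   # measured at the mean
  m$x_mean <- 5
  expect_equal(correct_variable(10, m, 3), 14)
  m$b <- 0
  expect_equal(correct_variable(10, m, 7), 10)
  # apply = FALSE leaves the value untouched
  m$b <- 2; m$apply <- FALSE
  expect_equal(correct_variable(10, m, 3), 10)
})

test_that("the correction is affine in Y with unit slope", {
  m <- structure(list(b = 1.7, x_mean = 4.2, r = 0.9, p = 0.001,
                      apply = TRUE, alpha = 0.05),
                 class = "correction_model")
  y <- c(3, 9, 12)
  delta <- 2.5
  expect_equal(correct_variable(y + delta, m, 6),
               correct_variable(y, m, 6) + delta)
})

test_that("analyze_recordings chains segmentation, features and correction", {
  locs <- demo_localities()[1:2]
  waves <- lapply(locs, synthesize_call)
  out <- analyze_recordings(waves)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_pulses, vapply(locs, function(p) p$n_pulses, 0L),
               ignore_attr = TRUE)
  # with a covariate table, corrected columns appear when screening passes
  waves3 <- lapply(demo_localities(), synthesize_call)
  cov <- data.frame(file = names(waves3), svl = c(30, 45, 38))
  out3 <- analyze_recordings(waves3, covariates = cov)
  expect_true(is.data.frame(out3))
})
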