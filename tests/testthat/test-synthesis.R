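fs <- 44100

test_that("call_parameters validates fields and duration consistency", {
  expect_error(call_parameters(0, 4, 0.1, 0.1, 50), "positive")
  expect_error(call_parameters(2000, 0, 0.1, 0.1, 50), "count")
  expect_error(call_parameters(2000, 4, 0.1, 0.1, 120), "0, 100")
  # call_duration off by more than 1% of the implied pulse structure
  expect_error(call_parameters(2000, 4, 0.1, 0.1, 50, call_duration = 0.8),
               "inconsistent")
  p <- call_parameters(2000, 4, 0.1, 0.1, 50)
  expect_equal(p$call_duration, 0.7)
  expect_equal(p$pulse_rate, 4 / 0.7)
})

test_that("an unmodulated pulse has a flat interior envelope", {
  p <- call_parameters(2000, 1, 0.1, 0, modulation_depth = 0,
                       n_intra_pulse_modulations = 5)
  w <- synthesize_pulse(p, fs)
  env <- compute_envelope(w)$values
  interior <- env[round(0.005 * fs):round(0.095 * fs)]
  depth <- 100 * (max(interior) - min(interior)) / max(interior)
  expect_lt(depth, 1)
})

test_that("five intra-pulse modulations produce five envelope dips", {
  p <- call_parameters(2000, 1, 0.1, 0, modulation_depth = 90,
                       n_intra_pulse_modulations = 5)
  w <- synthesize_pulse(p, fs)
  env <- compute_envelope(w)$values
  # count modulation cycles as sub-midline envelope runs in the interior
  interior <- env[round(0.003 * fs):round(0.097 * fs)]
  mid <- (max(interior) + min(interior)) / 2
  expect_identical(oracle_run_count(interior < mid), 5L)
})

test_that("the pulse spectral peak sits at the carrier frequency", {
  p <- call_parameters(2000, 1, 0.1, 0, modulation_depth = 0)
  w <- synthesize_pulse(p, fs)
  peak <- oracle_fft_peak(w$samples, fs)
  bin <- fs / length(w$samples)
  expect_lt(abs(peak - 2000), bin + 1e-9)
})

test_that("carrier at or above Nyquist and bad durations are rejected", {
  p <- call_parameters(23000, 1, 0.1, 0, 50)
  expect_error(synthesize_pulse(p, fs), "Nyquist")
})

test_that("a synthesized call re-segments into its constructed pulses", {
  p <- call_parameters(2000, 4, 0.1, 0.1, 80)
  w <- synthesize_call(p, fs)
  expect_equal(wave_duration(w), 0.7, tolerance = 1e-6)
  expect_equal(w$annotations, c(0, 0.2, 0.4, 0.6))
  seg <- segment_calls(compute_envelope(w), 0.1, 0.005, 0.5)
  expect_equal(nrow(seg$calls), 1)
  pulses <- seg$pulses[[1]]
  expect_equal(nrow(pulses), 4)
  expect_lt(max(abs(pulses$onset - w$annotations)), 0.001)
})

test_that("a single-pulse call equals the bare pulse", {
  p <- call_parameters(2000, 1, 0.1, 0, 50)
  expect_identical(synthesize_call(p, fs)$samples,
                   synthesize_pulse(p, fs)$samples)
})

test_that("localities differing only in carrier share an envelope", {
  a <- call_parameters(1800, 3, 0.05, 0.05, 70)
  b <- call_parameters(2600, 3, 0.05, 0.05, 70)
  wa <- synthesize_call(a, fs)
  wb <- synthesize_call(b, fs)
  ea <- compute_envelope(wa)$values
  eb <- compute_envelope(wb)$values
  expect_lt(sqrt(mean((ea - eb)^2)) / sqrt(mean(ea^2)), 0.02)
  expect_lt(abs(oracle_fft_peak(wa$samples, fs) - 1800), 10)
  expect_lt(abs(oracle_fft_peak(wb$samples, fs) - 2600), 10)
})

test_that("stimulus trains assemble replicates with the configured gaps", {
  p <- call_parameters(2000, 4, 0.1, 0.1, 80, call_duration = NULL)
  call <- waveform(rep(0.5, fs), fs)  # exactly 1 s
  train <- build_stimulus_train(call, stimulus_spec(5, 6))
  expect_equal(wave_duration(train), 5 * 1 + 4 * 6)
  expect_equal(train$annotations, 7 * (0:4))
  # n = 1 is the identity
  one <- build_stimulus_train(call, stimulus_spec(1, 6))
  expect_identical(one$samples, call$samples)
  # isi = 0 is plain concatenation
  cat0 <- build_stimulus_train(call, stimulus_spec(5, 0))
  expect_equal(length(cat0$samples), 5 * length(call$samples))
  expect_error(stimulus_spec(0, 6), "count")
})

test_that("synthesis is deterministic and never clips", {
  p <- call_parameters(2432.7, 7, 0.043, 0.061, 88)
  w1 <- synthesize_call(p, fs)
  w2 <- synthesize_call(p, fs)
  expect_identical(w1$samples, w2$samples)
  expect_lte(max(abs(w1$samples)), 1 - 2^-15)
})
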