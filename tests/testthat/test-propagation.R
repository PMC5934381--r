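fs <- 44100

test_that("spherical spreading loses 6 dB per doubling of distance", {
  expect_equal(round(geometric_attenuation_db(1, 0.5)), 6)
  expect_equal(geometric_attenuation_db(1, 0.5), 20 * log10(2))
  expect_equal(geometric_attenuation_db(0.5, 0.5), 0)
  expect_equal(geometric_attenuation_db(16, 0.5), 20 * log10(32))
  expect_error(geometric_attenuation_db(-1, 0.5), "positive")
  expect_error(geometric_attenuation_db(1, 2), ">=")
})

test_that("excess attenuation is a calibrated band-wise dB drop", {
  p <- call_parameters(2000, 3, 0.05, 0.05, 60)
  w <- synthesize_call(p, fs)
  # zero coefficients: identity
  bands0 <- data.frame(lower = 0, upper = fs / 2, coef = 0)
  w0 <- apply_excess_attenuation(w, bands0, 4, 0.5)
  expect_equal(w0$samples, w$samples, tolerance = 1e-10)
  # full-band 1 dB/m over 4 m: broadband RMS drops 4 dB
  bands1 <- data.frame(lower = 0, upper = fs / 2 + 1, coef = 1)
  w1 <- apply_excess_attenuation(w, bands1, 4.5, 0.5)
  drop_db <- 20 * log10(sqrt(mean(w$samples^2)) / sqrt(mean(w1$samples^2)))
  expect_equal(drop_db, 4, tolerance = 1e-6)
  # attenuating above 3 kHz leaves a 2 kHz carrier's peak in place
  bands2 <- data.frame(lower = 3000, upper = fs / 2 + 1, coef = 2)
  w2 <- apply_excess_attenuation(w, bands2, 8, 0.5)
  expect_lt(abs(oracle_fft_peak(w2$samples, fs) - 2000), 10)
  # overlapping bands rejected
  bad <- data.frame(lower = c(0, 2000), upper = c(3000, 4000), coef = c(1, 1))
  expect_error(apply_excess_attenuation(w, bad, 4, 0.5), "overlap")
})

test_that("reverberation fills gaps without creating energy", {
  p <- call_parameters(2000, 4, 0.05, 0.05, 85)
  w <- synthesize_call(p, fs)
  expect_identical(apply_reverberation(w, 0)$samples, w$samples)
  wr <- apply_reverberation(w, 0.05)
  expect_lte(sum(wr$samples^2), sum(w$samples^2) * (1 + 1e-9))
  # measured modulation depth strictly decreases
  md_clean <- transmitted_modulation_depth(w, 400)
  md_reverb <- transmitted_modulation_depth(wr, 400)
  expect_lt(md_reverb, md_clean)
  # an impulse returns the kernel itself, whose spectral gain never
  # exceeds one at any frequency
  imp <- waveform(c(1, numeric(fs / 2)), fs)
  out <- apply_reverberation(imp, 0.01)
  h <- reverb_kernel(0.01, fs)
  expect_equal(out$samples[seq_along(h)], h, tolerance = 1e-9)
  H <- Mod(fft(c(h, numeric(2^18 - length(h)))))
  expect_lte(max(H), 1)
})

test_that("background noise is seeded, calibrated and clip-guarded", {
  calib <- calibration_reference(tone_rms_digital = 0.05)
  w <- waveform(numeric(fs), fs)  # 1 s of silence: noise-only measurement
  n1 <- add_noise(w, 60, calib, seed = 9)
  n2 <- add_noise(w, 60, calib, seed = 9)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(add_noise(w, 60, calib, seed = 10)$samples,
                         n1$samples))
  # requested 60 dB measured within 0.5 dB
  expect_lt(abs(spl(n1, calib) - 60), 0.5)
  # noise off is the identity
  expect_identical(add_noise(w, -Inf, calib, seed = 9)$samples, w$samples)
  # clipping guard
  loud <- waveform(rep(0.999, 1000), fs)
  expect_error(add_noise(loud, 94, calib, seed = 1), "clip")
})

test_that("a lossless transect follows the spherical-spreading law", {
  p <- demo_localities()$south
  stim <- build_stimulus_train(synthesize_call(p), stimulus_spec(2, 0.5))
  rec <- simulate_transect(stim, transect_config(seed = 5))
  tbl <- measure_transect(rec, "t1", "south")
  lvl <- vapply(split(tbl$spl_db, tbl$distance), mean, 0)
  d <- as.numeric(names(lvl))
  expected_drop <- geometric_attenuation_db(d, 0.5)
  expect_equal(unname(lvl[1] - lvl), unname(expected_drop), tolerance = 0.001)
  # each doubling in the 2 -> 16 m chain loses 6.02 dB (0.5 -> 2 m is two)
  doubling <- c(lvl["0.5"] - lvl["2"], lvl["2"] - lvl["4"],
                lvl["4"] - lvl["8"], lvl["8"] - lvl["16"])
  expect_true(all(abs(doubling - c(12.04, 6.02, 6.02, 6.02)) < 0.05))
  # spectra unchanged: SCC between 0.5 m and 16 m is 1
  scc16 <- tbl$scc[tbl$distance == 16]
  expect_true(all(abs(scc16 - 1) < 0.01))
})

test_that("low-pass excess attenuation makes SCC non-increasing in distance", {
  p <- demo_localities()$central
  stim <- build_stimulus_train(synthesize_call(p), stimulus_spec(1, 0))
  cfg <- transect_config(
    excess_attenuation = data.frame(lower = 2000, upper = 22051, coef = 1.5),
    seed = 2)
  rec <- simulate_transect(stim, cfg)
  tbl <- measure_transect(rec, "t1", "central")
  sc <- tapply(tbl$scc, tbl$distance, mean)
  expect_true(all(diff(sc) <= 1e-9))
})

test_that("simulation is reproducible end-to-end from stimulus and config", {
  p <- demo_localities()$north
  stim <- build_stimulus_train(synthesize_call(p), stimulus_spec(1, 0))
  cfg <- transect_config(noise_level = 50, reverb_decay = 0.005, seed = 77)
  r1 <- simulate_transect(stim, cfg)
  r2 <- simulate_transect(stim, cfg)
  for (nm in names(r1$recordings))
    expect_identical(r1$recordings[[nm]]$samples, r2$recordings[[nm]]$samples)
})
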