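# Shared generators and independent oracles for the test-suite.

# Random but realistic call parameter sets (five intra-pulse modulations,
# carrier well below Nyquist, gaps comfortably between the pulse-bridging
# and call-splitting segmentation scales).
random_call_parameters <- function(label = "rand") {
  call_parameters(
    dominant_frequency = runif(1, 1500, 3500),
    n_pulses = sample(3:15, 1),
    pulse_duration = runif(1, 0.02, 0.08),
    inter_pulse_interval = runif(1, 0.03, 0.12),
    modulation_depth = runif(1, 0, 100),
    n_intra_pulse_modulations = 5,
    locality_label = label)
}

# Brute-force run-length pulse counter on a logical vector.
oracle_run_count <- function(mask) {
  n <- 0L
  prev <- FALSE
  for (v in mask) {
    if (v && !prev) n <- n + 1L
    prev <- v
  }
  n
}

# Zero-lag normalized cross-correlation, written out longhand.
oracle_zero_lag_r <- function(a, b) {
  am <- sum(a) / length(a)
  bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# FFT peak frequency of a signal (plain periodogram argmax).
oracle_fft_peak <- function(x, fs) {
  mag <- Mod(stats::fft(x))[seq_len(length(x) %/% 2 + 1)]
  (which.max(mag) - 1) * fs / length(x)
}

# Build a mean_power_spectrum object directly from a power vector.
make_mps <- function(power, fs = 44100, window_length = 440) {
  structure(list(power = power,
                 frequency = (seq_along(power) - 1) * fs / window_length,
                 bin_spacing = fs / window_length,
                 window_length = window_length,
                 window_type = "hanning",
                 overlap = 0),
            class = "mean_power_spectrum")
}

# Random degradation table: n_transects x origins x distances, one row per
# cell (replicates already averaged), optionally with a constant SSPL
# offset added to the local origin.
random_degradation_table <- function(n_transects = 5,
                                     origins = c("A", "B", "C"),
                                     distances = c(0.5, 2, 4, 8, 16),
                                     local = NULL, effect = 0) {
  g <- expand.grid(transect = paste0("T", seq_len(n_transects)),
                   origin = origins, distance = distances,
                   stringsAsFactors = FALSE)
  g$sspl <- runif(nrow(g), 0, 1)
  g$smd <- runif(nrow(g), 0, 1)
  g$scc <- runif(nrow(g), -1, 1)
  if (!is.null(local)) g$sspl[g$origin == local] <-
      g$sspl[g$origin == local] + effect
  g
}
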