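# Forward model of a playback transect: geometric spreading, band-wise
# excess attenuation, reverberant smearing and background noise.

#' Transect simulation configuration
#'
#' Parameters of the propagation forward model standing in for a field
#' transect: microphone distances, source level at the reference distance,
#' per-band excess-attenuation coefficients, reverberation decay and
#' broadband background-noise level.
#'
#' @param distances Microphone distances from the loudspeaker in metres,
#'   sorted ascending (default `c(0.5, 2, 4, 8, 16)`).
#' @param reference_distance Reference (closest) distance in metres
#'   (default 0.5).
#' @param source_level Calibrated level of the stimulus at the reference
#'   distance, dB SPL (default 90).
#' @param excess_attenuation Data frame with columns `lower`, `upper` (band
#'   edges, Hz) and `coef` (dB per metre beyond the reference distance), or
#'   `NULL` for none. Bands must not overlap.
#' @param reverb_decay Exponential reverberation time constant in seconds
#'   (0 = off).
#' @param noise_level Broadband background-noise level in dB SPL; `-Inf`
#'   disables noise.
#' @param noise_lead Duration of the noise-only segment prepended to each
#'   recording, seconds (default 0.5).
#' @param seed Integer seed for the noise generator.
#' @return An object of class `transect_config`.
#' @export
transect_config <- function(distances = c(0.5, 2, 4, 8, 16),
                            reference_distance = 0.5,
                            source_level = 90,
                            excess_attenuation = NULL,
                            reverb_decay = 0,
                            noise_level = -Inf,
                            noise_lead = 0.5,
                            seed = 1) {
  if (is.unsorted(distances, strictly = TRUE))
    stop("'distances' must be strictly ascending")
  if (any(distances < reference_distance) || reference_distance <= 0)
    stop("all distances must be >= reference_distance > 0")
  if (!is.null(excess_attenuation)) {
    ea <- excess_attenuation
    if (!all(c("lower", "upper", "coef") %in% names(ea)))
      stop("'excess_attenuation' needs columns lower, upper, coef")
    if (any(ea$coef < 0)) stop("excess-attenuation coefficients must be >= 0")
    o <- order(ea$lower)
    if (nrow(ea) > 1 && any(ea$upper[o][-nrow(ea)] > ea$lower[o][-1]))
      stop("excess-attenuation bands overlap")
  }
  if (reverb_decay < 0) stop("'reverb_decay' must be >= 0")
  structure(list(distances = distances,
                 reference_distance = reference_distance,
                 source_level = source_level,
                 excess_attenuation = excess_attenuation,
                 reverb_decay = reverb_decay,
                 noise_level = noise_level,
                 noise_lead = noise_lead,
                 seed = seed),
            class = "transect_config")
}

#' Geometric (spherical-spreading) attenuation
#'
#' Attenuation of a point source in free field relative to a reference
#' distance: `20 * log10(d / d_ref)` dB, i.e. a 6-dB amplitude loss per
#' doubling of distance.
#'
#' @param d Distance in metres (`d >= d_ref`).
#' @param d_ref Reference distance in metres (> 0).
#' @return Attenuation in dB (vectorized over `d`).
#' @export
geometric_attenuation_db <- function(d, d_ref) {
  if (any(d_ref <= 0) || any(d <= 0)) stop("distances must be positive")
  if (any(d < d_ref)) stop("'d' must be >= 'd_ref'")
  20 * log10(d / d_ref)
}

#' Apply band-wise excess attenuation
#'
#' Attenuates each configured frequency band by `coef * (d - d_ref)` dB via a
#' zero-phase piecewise spectral filter (gains applied symmetrically in the
#' frequency domain, so pulse onsets are not shifted). Frequencies outside
#' all bands pass unchanged.
#'
#' @param wave A [waveform()].
#' @param bands Data frame with columns `lower`, `upper` (Hz) and `coef`
#'   (dB/m); `NULL` is the identity.
#' @param d,d_ref Distance and reference distance in metres.
#' @return Filtered [waveform()].
#' @export
apply_excess_attenuation <- function(wave, bands, d, d_ref) {
  stopifnot(inherits(wave, "waveform"))
  if (is.null(bands) || nrow(bands) == 0 || d == d_ref) return(wave)
  nyq <- wave$sample_rate / 2
  if (any(bands$lower > nyq))
    stop("excess-attenuation band edges above Nyquist")
  o <- order(bands$lower)
  if (nrow(bands) > 1 && any(bands$upper[o][-nrow(bands)] > bands$lower[o][-1]))
    stop("excess-attenuation bands overlap")
  n <- length(wave$samples)
  f <- (seq_len(n) - 1) * wave$sample_rate / n
  f <- pmin(f, wave$sample_rate - f)  # fold to [0, fs/2]
  gain <- rep(1, n)
  for (i in seq_len(nrow(bands))) {
    sel <- f >= bands$lower[i] & f < bands$upper[i]
    gain[sel] <- db_to_amp(-bands$coef[i] * (d - d_ref))
  }
  y <- Re(stats::fft(stats::fft(wave$samples) * gain, inverse = TRUE) / n)
  out <- wave
  out$samples <- y
  out
}

# Reverberation impulse response: a unit direct path followed by a diffuse
# reflection tail (fixed pseudo-random signs, so the kernel is deterministic)
# whose magnitude decays exponentially with time constant `decay`, truncated
# at six time constants.  The kernel is normalized by its peak spectral
# magnitude (with margin) so that no frequency band is amplified -- signal
# energy can never increase through this stage.
reverb_kernel <- function(decay, fs) {
  L <- max(2, round(6 * decay * fs))
  env <- exp(-(seq_len(L) - 1) / (decay * fs))
  tail <- withr::with_seed(914581, stats::rnorm(L)) * env
  tail <- tail / sqrt(sum(tail^2))        # tail energy equals the direct path
  h <- c(1, numeric(L - 1)) + c(0, tail[-1])
  H <- Mod(stats::fft(c(h, numeric(next_pow2(4 * L) - L))))
  h / (1.01 * max(H))
}

#' Apply reverberant smearing
#'
#' Convolves the signal with a reverberation impulse response: a direct-path
#' impulse followed by a diffuse reflection tail whose magnitude decays
#' exponentially with time constant `decay` (truncated at six time
#' constants). The kernel is deterministic and normalized so that its
#' spectral gain never exceeds one: reverberation fills inter-pulse gaps and
#' reduces the measured modulation depth, but can never increase signal
#' energy. `decay = 0` is the identity.
#'
#' @param wave A [waveform()].
#' @param decay Exponential time constant in seconds (>= 0).
#' @return Reverberated [waveform()] (same length as the input).
#' @export
apply_reverberation <- function(wave, decay) {
  stopifnot(inherits(wave, "waveform"))
  if (decay < 0) stop("'decay' must be >= 0")
  if (decay == 0) return(wave)
  fs <- wave$sample_rate
  h <- reverb_kernel(decay, fs)
  L <- length(h)
  n <- length(wave$samples)
  nfft <- next_pow2(n + L - 1)
  X <- stats::fft(c(wave$samples, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
  out <- wave
  out$samples <- y
  out
}

#' Add calibrated Gaussian background noise
#'
#' Adds stationary white Gaussian noise whose calibrated broadband level is
#' `noise_level` dB SPL under the supplied calibration reference. Seeded and
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param wave A [waveform()].
#' @param noise_level Desired noise level in dB SPL; `-Inf` returns the
#'   input unchanged.
#' @param calib A [calibration_reference()] mapping digital RMS to dB SPL.
#' @param seed Integer seed.
#' @return Noisy [waveform()].
#' @export
add_noise <- function(wave, noise_level, calib, seed) {
  stopifnot(inherits(wave, "waveform"))
  if (identical(noise_level, -Inf)) return(wave)
  stopifnot(inherits(calib, "calibration_reference"))
  sigma <- calib$tone_rms_digital * db_to_amp(noise_level - calib$tone_level)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(wave$samples), 0, sigma))
  y <- wave$samples + noise
  if (max(abs(y)) > 1)
    stop("noise addition would clip; lower noise_level or source amplitude")
  out <- wave
  out$samples <- y
  out
}

#' Simulate a propagation transect
#'
#' Produces one calibrated recording per configured distance: the stimulus is
#' scaled by geometric spreading relative to the reference distance, filtered
#' by the band-wise excess attenuation, reverberated, padded with a leading
#' noise-only segment, and embedded in calibrated background noise. A single
#' calibration constant (digital RMS at 94 dB SPL) is chosen so that the
#' stimulus at the reference distance measures `source_level` dB SPL, and is
#' shared by all channels of the transect.
#'
#' @param stimulus A [build_stimulus_train()] output (replicate onsets in its
#'   annotations are propagated into per-distance markers).
#' @param config A [transect_config()].
#' @return An object of class `transect_recording`: `recordings` (named list
#'   of [waveform()]s, one per distance), `calibration` (a
#'   [calibration_reference()]), `markers` (data frame of noise span and
#'   replicate spans per distance, seconds) and `config`.
#' @export
simulate_transect <- function(stimulus, config) {
  stopifnot(inherits(stimulus, "waveform"), inherits(config, "transect_config"))
  if (length(stimulus$samples) < 1) stop("empty stimulus")
  fs <- stimulus$sample_rate
  onsets <- stimulus$annotations
  if (is.null(onsets)) onsets <- 0
  rep_dur <- attr(stimulus, "replicate_duration")
  if (is.null(rep_dur)) rep_dur <- wave_duration(stimulus)

  # calibration: active-span RMS of the reference-distance stimulus maps to
  # source_level dB SPL
  active <- unlist(lapply(onsets, function(o) {
    (round(o * fs) + 1):min(length(stimulus$samples), round((o + rep_dur) * fs))
  }))
  tone_rms <- rms(stimulus$samples[active]) *
    db_to_amp(94 - config$source_level)
  calib <- calibration_reference(tone_rms_digital = tone_rms)

  n_lead <- round(config$noise_lead * fs)
  recs <- list()
  markers <- list()
  for (i in seq_along(config$distances)) {
    d <- config$distances[i]
    geo <- geometric_attenuation_db(d, config$reference_distance)
    w <- stimulus
    w$samples <- stimulus$samples * db_to_amp(-geo)
    w <- apply_excess_attenuation(w, config$excess_attenuation, d,
                                  config$reference_distance)
    w <- apply_reverberation(w, config$reverb_decay)
    w$samples <- c(numeric(n_lead), w$samples)
    w$annotations <- config$noise_lead + onsets
    w <- add_noise(w, config$noise_level, calib,
                   child_seed(config$seed, i))
    recs[[sprintf("%gm", d)]] <- w
    markers[[i]] <- data.frame(
      distance = d,
      replicate = seq_along(onsets),
      onset_s = config$noise_lead + onsets,
      duration_s = rep_dur,
      noise_onset_s = 0,
      noise_duration_s = config$noise_lead)
  }
  structure(list(recordings = recs,
                 calibration = calib,
                 markers = do.call(rbind, markers),
                 config = config),
            class = "transect_recording")
}

#' @export
print.transect_recording <- function(x, ...) {
  cat(sprintf("<transect_recording> %d distances (%s m), %d replicates\n",
              length(x$recordings),
              paste(x$config$distances, collapse = ", "),
              max(x$markers$replicate)))
  invisible(x)
}
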