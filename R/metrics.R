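# SPL calibration, noise correction, mean power spectra, spectral
# cross-correlation and transmitted modulation depth.

#' Calibration reference
#'
#' Maps digital RMS amplitude to absolute sound pressure level via a
#' reference tone: `SPL(x) = tone_level + 20 * log10(rms(x) / tone_rms_digital)`.
#'
#' @param tone_rms_digital Digital RMS of the calibration-tone segment (> 0).
#' @param tone_level Level of the calibrator tone in dB SPL (default 94).
#' @param tone_frequency Calibrator tone frequency in Hz (default 1000).
#' @return An object of class `calibration_reference`.
#' @export
calibration_reference <- function(tone_rms_digital, tone_level = 94,
                                  tone_frequency = 1000) {
  if (!is_scalar(tone_rms_digital) || tone_rms_digital <= 0)
    stop("'tone_rms_digital' must be positive")
  structure(list(tone_rms_digital = tone_rms_digital,
                 tone_level = tone_level,
                 tone_frequency = tone_frequency),
            class = "calibration_reference")
}

#' Derive a calibration reference from a recorded calibrator tone
#'
#' Measures the digital RMS of a recorded 1-kHz, 94-dB-SPL calibrator-tone
#' segment and anchors the digital-to-SPL map to it. If the segment's
#' spectral peak is not within 50 Hz of the nominal tone frequency, a warning
#' is issued and the reference is still returned.
#'
#' @param tone_segment A [waveform()] at least 0.1 s long containing the
#'   calibrator tone.
#' @param tone_level Calibrator level in dB SPL (default 94).
#' @param tone_frequency Nominal tone frequency in Hz (default 1000).
#' @return A [calibration_reference()].
#' @export
calibrate <- function(tone_segment, tone_level = 94, tone_frequency = 1000) {
  stopifnot(inherits(tone_segment, "waveform"))
  fs <- tone_segment$sample_rate
  if (wave_duration(tone_segment) < 0.1)
    stop("calibration segment shorter than 0.1 s")
  r <- rms(tone_segment$samples)
  if (r <= 0) stop("silent calibration segment")
  peak <- pulse_dominant_frequency(tone_segment$samples, fs, 0,
                                   wave_duration(tone_segment))
  if (abs(peak - tone_frequency) > 50)
    warning(sprintf(
      "calibration-tone peak at %.0f Hz, expected %.0f +/- 50 Hz; proceeding",
      peak, tone_frequency))
  calibration_reference(r, tone_level, tone_frequency)
}

#' Calibrated sound pressure level of a segment
#'
#' @param segment A [waveform()] (or numeric sample vector).
#' @param calib A [calibration_reference()].
#' @return SPL in dB (`-Inf` for a silent segment).
#' @export
spl <- function(segment, calib) {
  stopifnot(inherits(calib, "calibration_reference"))
  x <- if (inherits(segment, "waveform")) segment$samples else segment
  calib$tone_level + 20 * log10(rms(x) / calib$tone_rms_digital)
}

#' Noise-corrected sound pressure level
#'
#' Removes the background-noise contribution from the level of a call
#' embedded in noise by power subtraction:
#' `L = 10 * log10(10^(Lmeas/10) - 10^(Lnoise/10))`, with `Lmeas` measured on
#' the call-plus-noise segment and `Lnoise` on a contiguous noise-only
#' segment under the same calibration. When the noise level reaches or
#' exceeds the measured level the signal is below the noise floor and the
#' result is flagged missing (`NA`), never silently returned.
#'
#' @param call_segment Call-plus-noise [waveform()] (or samples).
#' @param noise_segment Contiguous noise-only [waveform()] (or samples).
#' @param calib A [calibration_reference()] shared by both segments.
#' @return Noise-corrected SPL in dB, or `NA` if the signal is at or below
#'   the noise floor.
#' @export
noise_corrected_spl <- function(call_segment, noise_segment, calib) {
  l_meas <- spl(call_segment, calib)
  l_noise <- spl(noise_segment, calib)
  if (l_noise == -Inf) return(l_meas)
  if (l_noise >= l_meas) return(NA_real_)
  10 * log10(10^(l_meas / 10) - 10^(l_noise / 10))
}

#' Mean power spectrum over non-overlapping Hanning windows
#'
#' Averages per-window power spectra over consecutive, non-overlapping
#' Hanning windows (0% overlap; the trailing partial window is discarded).
#' With the default 440-point window at 44.1 kHz the frequency resolution is
#' 44100/440 = 100.227 Hz and the temporal resolution 440/44100 = 9.977 ms.
#'
#' @param segment A [waveform()].
#' @param window_length Window length in samples (default 440).
#' @return An object of class `mean_power_spectrum`: `power` (linear power
#'   per one-sided bin), `frequency` (Hz), `bin_spacing`, `window_length`,
#'   `window_type`, `overlap`.
#' @export
mean_power_spectrum <- function(segment, window_length = 440) {
  stopifnot(inherits(segment, "waveform"))
  x <- segment$samples
  n <- length(x)
  if (n < window_length)
    stop("segment shorter than one analysis window")
  fs <- segment$sample_rate
  nwin <- n %/% window_length
  w <- hann_window(window_length)
  m <- matrix(x[seq_len(nwin * window_length)], nrow = window_length) * w
  P <- Mod(stats::mvfft(m))^2
  nb <- window_length %/% 2 + 1
  power <- rowMeans(P[seq_len(nb), , drop = FALSE])
  structure(list(power = power,
                 frequency = (seq_len(nb) - 1) * fs / window_length,
                 bin_spacing = fs / window_length,
                 window_length = window_length,
                 window_type = "hanning",
                 overlap = 0),
            class = "mean_power_spectrum")
}

#' Spectral cross-correlation at zero lag
#'
#' Pearson correlation between two mean power spectra on identical bin
#' grids, used as the spectral-degradation index between the reference
#' (0.5 m) recording and a farther one. Spectra are restricted to the call
#' energy band (0-10 kHz by default) before correlating; `scale = "dB"`
#' correlates decibel-transformed powers instead of linear ones.
#'
#' @param spec_ref,spec_far [mean_power_spectrum()] objects on the same grid.
#' @param freq_range Length-2 numeric band (Hz) retained before correlating;
#'   `NULL` for full band.
#' @param scale `"linear"` (default) or `"dB"`.
#' @return Correlation coefficient in `[-1, 1]`; `NA` if either spectrum is
#'   constant over the retained band.
#' @export
scc <- function(spec_ref, spec_far, freq_range = c(0, 10000),
                scale = c("linear", "dB")) {
  stopifnot(inherits(spec_ref, "mean_power_spectrum"),
            inherits(spec_far, "mean_power_spectrum"))
  scale <- match.arg(scale)
  if (length(spec_ref$power) != length(spec_far$power) ||
      !isTRUE(all.equal(spec_ref$frequency, spec_far$frequency)))
    stop("spectra are on different bin grids")
  keep <- rep(TRUE, length(spec_ref$power))
  if (!is.null(freq_range))
    keep <- spec_ref$frequency >= freq_range[1] &
      spec_ref$frequency <= freq_range[2]
  a <- spec_ref$power[keep]
  b <- spec_far$power[keep]
  if (scale == "dB") {
    floor_p <- max(c(a, b)) * 1e-12
    a <- 10 * log10(pmax(a, floor_p))
    b <- 10 * log10(pmax(b, floor_p))
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Transmitted modulation depth of a recorded call segment
#'
#' Envelope via the Hilbert modulus, smoothed by averaging over
#' non-overlapping windows (400 samples, 0% overlap, by default), then depth
#' `100 * (max - min) / max` within the pulse. The pulse interior is taken
#' between the first and last smoothed-envelope values of at least half the
#' segment's envelope maximum, which excludes partially filled boundary
#' windows while retaining all intra-pulse modulation dips.
#'
#' @param segment A [waveform()] containing at least one pulse.
#' @param smoothing_window Envelope smoothing window in samples (default
#'   400).
#' @return Modulation depth in percent (amplitude-scale invariant).
#' @export
transmitted_modulation_depth <- function(segment, smoothing_window = 400) {
  stopifnot(inherits(segment, "waveform"))
  if (length(segment$samples) < smoothing_window)
    stop("segment shorter than the smoothing window")
  env <- compute_envelope(segment, smoothing_window)$values
  mx <- max(env)
  if (mx <= 0) return(0)
  idx <- which(env >= 0.5 * mx)
  interior <- env[min(idx):max(idx)]
  100 * (max(interior) - min(interior)) / max(interior)
}
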