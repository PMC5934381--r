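#' Per-locality call parameter set
#'
#' Bundles the seven call variables (plus the intra-pulse modulation count)
#' that describe the average advertisement call of one locality, and that
#' drive both synthesis and the expected output of analysis.  `call_duration`
#' and `pulse_rate` may be omitted and are then derived from the pulse-level
#' fields; when supplied they must be consistent with
#' `n_pulses * pulse_duration + (n_pulses - 1) * inter_pulse_interval`
#' within 1%.
#'
#' @param dominant_frequency Carrier (spectral peak) frequency, Hz.
#' @param n_pulses Number of pulses in the call.
#' @param pulse_duration Duration of one pulse, seconds.
#' @param inter_pulse_interval Silent gap between consecutive pulses, seconds.
#' @param modulation_depth Intra-pulse amplitude modulation depth, percent:
#'   `100 * (max - min) / max` of the pulse envelope.
#' @param n_intra_pulse_modulations Number of envelope modulation cycles
#'   within one pulse (five in typical advertisement calls of the study
#'   species).
#' @param call_duration Total call duration, seconds (optional; derived).
#' @param pulse_rate Pulses per second (optional; derived as
#'   `n_pulses / call_duration`).
#' @param locality_label Free-text label for the locality of origin.
#'
#' @return An object of class `call_parameters`.
#' @export
call_parameters <- function(dominant_frequency, n_pulses, pulse_duration,
                            inter_pulse_interval, modulation_depth,
                            n_intra_pulse_modulations = 5,
                            call_duration = NULL, pulse_rate = NULL,
                            locality_label = "unlabelled") {
  if (!is_scalar(dominant_frequency) || dominant_frequency <= 0)
    stop("'dominant_frequency' must be positive")
  if (!is_count(n_pulses) || n_pulses < 1)
    stop("'n_pulses' must be a count >= 1")
  if (!is_scalar(pulse_duration) || pulse_duration <= 0)
    stop("'pulse_duration' must be positive")
  if (!is_scalar(inter_pulse_interval) || inter_pulse_interval < 0)
    stop("'inter_pulse_interval' must be >= 0")
  if (!is_scalar(modulation_depth) || modulation_depth < 0 ||
      modulation_depth > 100)
    stop("'modulation_depth' must lie in [0, 100]")
  if (!is_count(n_intra_pulse_modulations) || n_intra_pulse_modulations < 0)
    stop("'n_intra_pulse_modulations' must be a count >= 0")
  implied <- n_pulses * pulse_duration + (n_pulses - 1) * inter_pulse_interval
  if (is.null(call_duration)) {
    call_duration <- implied
  } else if (abs(call_duration - implied) > 0.01 * implied) {
    stop(sprintf(
      "'call_duration' (%.4f s) inconsistent with pulse structure (%.4f s)",
      call_duration, implied))
  }
  if (is.null(pulse_rate)) pulse_rate <- n_pulses / call_duration
  structure(
    list(dominant_frequency = dominant_frequency,
         call_duration = call_duration,
         n_pulses = as.integer(n_pulses),
         pulse_duration = pulse_duration,
         inter_pulse_interval = inter_pulse_interval,
         pulse_rate = pulse_rate,
         modulation_depth = modulation_depth,
         n_intra_pulse_modulations = as.integer(n_intra_pulse_modulations),
         locality_label = locality_label),
    class = "call_parameters")
}

#' @export
print.call_parameters <- function(x, ...) {
  cat(sprintf(
    "<call_parameters> '%s': %d pulses x %.0f ms (ipi %.0f ms), %.3f s call\n",
    x$locality_label, x$n_pulses, 1000 * x$pulse_duration,
    1000 * x$inter_pulse_interval, x$call_duration))
  cat(sprintf("  carrier %.0f Hz, depth %.0f%%, %d intra-pulse modulations\n",
              x$dominant_frequency, x$modulation_depth,
              x$n_intra_pulse_modulations))
  invisible(x)
}

#' Playback stimulus specification
#'
#' @param n_replicates Number of stimulus repetitions (default 5).
#' @param inter_stimulus_interval Silent gap between repetitions in seconds
#'   (default 6).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_replicates = 5, inter_stimulus_interval = 6) {
  if (!is_count(n_replicates) || n_replicates < 1)
    stop("'n_replicates' must be a count >= 1")
  if (!is_scalar(inter_stimulus_interval) || inter_stimulus_interval < 0)
    stop("'inter_stimulus_interval' must be >= 0")
  structure(list(n_replicates = as.integer(n_replicates),
                 inter_stimulus_interval = inter_stimulus_interval),
            class = "stimulus_spec")
}

#' Synthesize one amplitude-modulated pulse
#'
#' Builds a single call pulse: a sinusoidal carrier at the dominant
#' frequency, shaped by a raised-cosine intra-pulse modulator producing
#' `n_intra_pulse_modulations` envelope cycles across the pulse, and gated by
#' short cosine rise/fall ramps.  The modulator is
#' `e(t) = 1 - (d/100) * (1 - cos(2*pi*k*t/T)) / 2`, so the envelope's
#' `100 * (max - min) / max` equals the requested depth `d` exactly (measured
#' on the pulse interior, away from the gating ramps).
#'
#' @param params A [call_parameters()] object.
#' @param sample_rate Sampling rate, Hz (default 44100). The carrier must be
#'   below the Nyquist frequency.
#' @param amplitude Peak amplitude of the pulse (default 0.9; must stay below
#'   full scale so 16-bit export never clips).
#' @param ramp Rise/fall gate duration in seconds (default 2 ms).
#'
#' @return A [waveform()] containing the pulse.
#' @export
synthesize_pulse <- function(params, sample_rate = 44100, amplitude = 0.9,
                             ramp = 0.002) {
  stopifnot(inherits(params, "call_parameters"))
  if (params$dominant_frequency >= sample_rate / 2)
    stop("carrier at or above Nyquist frequency")
  if (params$pulse_duration <= 0) stop("non-positive pulse duration")
  if (amplitude <= 0 || amplitude > 1 - 2^-15)
    stop("'amplitude' must lie in (0, 1 - 2^-15]")
  n <- round(params$pulse_duration * sample_rate)
  if (n < 2) stop("pulse shorter than two samples at this rate")
  t <- (seq_len(n) - 1) / sample_rate
  carrier <- sin(2 * pi * params$dominant_frequency * t)
  d <- params$modulation_depth / 100
  k <- params$n_intra_pulse_modulations
  modulator <- if (k > 0 && d > 0) {
    1 - d * (1 - cos(2 * pi * k * t / params$pulse_duration)) / 2
  } else rep(1, n)
  gate <- rep(1, n)
  nr <- min(round(ramp * sample_rate), floor(n / 2))
  if (nr > 0) {
    r <- (1 - cos(pi * (seq_len(nr) - 0.5) / nr)) / 2
    gate[seq_len(nr)] <- r
    gate[n + 1 - seq_len(nr)] <- r
  }
  waveform(amplitude * carrier * modulator * gate, sample_rate,
           annotations = 0)
}

#' Synthesize a complete advertisement call
#'
#' Concatenates `n_pulses` identical pulses separated by
#' `inter_pulse_interval` seconds of silence.  Pulse onset times are recorded
#' in the waveform's annotations.
#'
#' @inheritParams synthesize_pulse
#' @return A [waveform()] with pulse onsets (seconds) in `annotations`.
#' @export
synthesize_call <- function(params, sample_rate = 44100, amplitude = 0.9,
                            ramp = 0.002) {
  stopifnot(inherits(params, "call_parameters"))
  pulse <- synthesize_pulse(params, sample_rate, amplitude, ramp)
  np <- params$n_pulses
  if (np == 1) return(pulse)
  n_pulse <- length(pulse$samples)
  period_s <- params$pulse_duration + params$inter_pulse_interval
  # place each onset on the true time grid (no cumulative rounding drift)
  onsets_idx <- round((seq_len(np) - 1) * period_s * sample_rate)
  total <- onsets_idx[np] + n_pulse
  x <- numeric(total)
  for (o in onsets_idx) x[o + seq_len(n_pulse)] <- pulse$samples
  waveform(x, sample_rate, annotations = onsets_idx / sample_rate)
}

#' Assemble a playback stimulus train
#'
#' Repeats a call `n_replicates` times with `inter_stimulus_interval` seconds
#' of silence between copies (gaps between copies only; no leading or
#' trailing silence).  Replicate onsets are annotated, and the single-call
#' duration is attached as the `replicate_duration` attribute for downstream
#' per-replicate measurement windows.
#'
#' @param call A [waveform()] holding one call.
#' @param spec A [stimulus_spec()].
#' @return A [waveform()]; `annotations` hold replicate onsets in seconds.
#' @export
build_stimulus_train <- function(call, spec = stimulus_spec()) {
  stopifnot(inherits(call, "waveform"), inherits(spec, "stimulus_spec"))
  if (length(call$samples) < 1) stop("empty call")
  n_rep <- spec$n_replicates
  fs <- call$sample_rate
  n_call <- length(call$samples)
  n_gap <- round(spec$inter_stimulus_interval * fs)
  period <- n_call + n_gap
  total <- n_rep * n_call + (n_rep - 1) * n_gap
  x <- numeric(total)
  onsets_idx <- (seq_len(n_rep) - 1) * period
  for (o in onsets_idx) x[o + seq_len(n_call)] <- call$samples
  out <- waveform(x, fs, annotations = onsets_idx / fs)
  attr(out, "replicate_duration") <- n_call / fs
  out
}
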