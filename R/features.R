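#' Extract the seven call variables from a segmented recording
#'
#' For every call in the segmentation, measures:
#' \itemize{
#'   \item `call_duration`: last pulse offset minus first pulse onset (s);
#'   \item `n_pulses`: pulse count;
#'   \item `mean_pulse_duration`: mean pulse span length (s);
#'   \item `mean_inter_pulse_interval`: mean offset-to-onset gap between
#'     consecutive pulses (s; `NA` for single-pulse calls);
#'   \item `pulse_rate`: `n_pulses / call_duration` (pulses/s);
#'   \item `modulation_depth`: `100 * (max - min) / max` of the Hilbert
#'     envelope within the central pulse, measured on the pulse interior
#'     (`edge_exclude` seconds trimmed from each end so gating ramps do not
#'     masquerade as modulation);
#'   \item `dominant_frequency`: frequency of the magnitude-spectrum peak of
#'     the central pulse (Hann-windowed, zero-padded).
#' }
#' The central pulse of an n-pulse call is pulse `ceiling(n / 2)` (1-based).
#'
#' @param wave The [waveform()] the segmentation was derived from.
#' @param seg A [segment_calls()] result for `wave`.
#' @param fft_length FFT length for the dominant-frequency spectrum; default
#'   `NULL` zero-pads the pulse to the next power of two and at least 4096
#'   samples for stable peak location.
#' @param edge_exclude Interior trim in seconds applied to each end of the
#'   central pulse before measuring modulation depth (default 2 ms, matching
#'   the synthesis gate).
#' @return A data frame with one row per call: `call_index`, `onset_s`, and
#'   the seven variables above.
#' @export
extract_features <- function(wave, seg, fft_length = NULL,
                             edge_exclude = 0.002) {
  stopifnot(inherits(wave, "waveform"), inherits(seg, "call_segmentation"))
  fs <- wave$sample_rate
  n_calls <- nrow(seg$calls)
  out <- vector("list", n_calls)
  if (n_calls == 0)
    return(data.frame(call_index = integer(0), onset_s = numeric(0),
                      call_duration = numeric(0), n_pulses = integer(0),
                      mean_pulse_duration = numeric(0),
                      mean_inter_pulse_interval = numeric(0),
                      pulse_rate = numeric(0), modulation_depth = numeric(0),
                      dominant_frequency = numeric(0)))
  env <- Mod(analytic_signal(wave$samples))
  for (ci in seq_len(n_calls)) {
    p <- seg$pulses[[ci]]
    np <- nrow(p)
    dur <- max(p$offset) - min(p$onset)
    if (dur <= 0) stop("call ", ci, " has zero duration")
    ipi <- if (np > 1) mean(p$onset[-1] - p$offset[-np]) else NA_real_
    central <- p[ceiling(np / 2), ]
    out[[ci]] <- data.frame(
      call_index = ci,
      onset_s = min(p$onset),
      call_duration = dur,
      n_pulses = np,
      mean_pulse_duration = mean(p$offset - p$onset),
      mean_inter_pulse_interval = ipi,
      pulse_rate = np / dur,
      modulation_depth = pulse_modulation_depth(env, fs, central$onset,
                                                central$offset, edge_exclude),
      dominant_frequency = pulse_dominant_frequency(
        wave$samples, fs, central$onset, central$offset, fft_length))
  }
  do.call(rbind, out)
}

# Depth of an envelope segment, interior-trimmed.  Falls back to the full
# span when the trim would empty it.
pulse_modulation_depth <- function(env, fs, onset, offset, edge_exclude) {
  i0 <- round((onset + edge_exclude) * fs) + 1
  i1 <- round((offset - edge_exclude) * fs)
  if (i1 <= i0) {
    i0 <- round(onset * fs) + 1
    i1 <- round(offset * fs)
  }
  seg <- env[max(1, i0):min(length(env), i1)]
  mx <- max(seg)
  if (mx <= 0) return(0)
  100 * (mx - min(seg)) / mx
}

# Spectral-peak frequency of a pulse: Hann window, zero-padded FFT.
pulse_dominant_frequency <- function(samples, fs, onset, offset,
                                     fft_length = NULL) {
  i0 <- round(onset * fs) + 1
  i1 <- min(length(samples), round(offset * fs))
  x <- samples[i0:i1]
  n <- length(x)
  nfft <- if (is.null(fft_length)) max(4096, next_pow2(n)) else fft_length
  xw <- x * hann_window(n)
  mag <- Mod(stats::fft(c(xw, numeric(nfft - n))))[seq_len(nfft %/% 2 + 1)]
  (which.max(mag) - 1) * fs / nfft
}

#' Fit a covariate-correction model for a call variable
#'
#' Regresses a call variable on a covariate (water temperature for the
#' temporal variables; snout-vent length for dominant frequency) by ordinary
#' least squares and screens it by the Pearson correlation: the correction is
#' applied only when the correlation is significant at `alpha`.
#'
#' @param y Numeric vector of call-variable values.
#' @param x Numeric vector of covariate values (same length, not constant).
#' @param alpha Two-sided significance level for the screening correlation
#'   (default 0.05).
#' @return An object of class `correction_model` with fields `b` (slope),
#'   `x_mean` (covariate grand mean), `r`, `p` and `apply`.
#' @export
fit_correction <- function(y, x, alpha = 0.05) {
  if (length(y) != length(x)) stop("'y' and 'x' lengths differ")
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("covariate is constant")
  if (stats::sd(y) == 0) {
    model <- list(b = 0, x_mean = mean(x), r = 0, p = 1,
                  apply = FALSE, alpha = alpha)
  } else {
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    model <- list(b = unname(stats::coef(fit)[2]), x_mean = mean(x),
                  r = unname(ct$estimate), p = ct$p.value,
                  apply = ct$p.value < alpha, alpha = alpha)
  }
  structure(model, class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> b = %.4g, x_mean = %.4g, r = %.3f (p = %.3g) -> %s\n",
    x$b, x$x_mean, x$r, x$p,
    if (x$apply) "correction applied" else "no correction"))
  invisible(x)
}

#' Adjust a call variable to the covariate grand mean
#'
#' Applies `Ycorr = Y - b * Xmeasured + b * Xmean` when the fitted model's
#' screening correlation was significant; otherwise returns `y` unchanged.
#' The correction is affine in `Y` with unit slope, so differences between
#' calls are preserved.
#'
#' @param y Call-variable value(s).
#' @param model A [fit_correction()] result.
#' @param x_measured Covariate value(s) measured alongside `y`.
#' @return Corrected value(s), same length as `y`.
#' @export
correct_variable <- function(y, model, x_measured) {
  stopifnot(inherits(model, "correction_model"))
  if (!model$apply) return(y)
  y - model$b * x_measured + model$b * model$x_mean
}
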