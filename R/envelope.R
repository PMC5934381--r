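# Hilbert-envelope computation and call/pulse segmentation.

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a waveform
#'
#' Computes the instantaneous-amplitude envelope as the modulus of the
#' analytic signal (Hilbert transform), optionally smoothed by averaging over
#' non-overlapping windows of `smoothing_window` samples (0% overlap; the
#' trailing partial window is discarded).  `smoothing_window = 1` returns the
#' raw Hilbert modulus.
#'
#' @param wave A [waveform()].
#' @param smoothing_window Smoothing window length in samples (>= 1).
#' @return An object of class `envelope` with fields `values` (non-negative
#'   amplitudes), `sample_rate_effective` (Hz after decimation-by-averaging)
#'   and `smoothing_window`.
#' @export
compute_envelope <- function(wave, smoothing_window = 1) {
  stopifnot(inherits(wave, "waveform"))
  n <- length(wave$samples)
  if (n < 1) stop("empty waveform")
  if (!is_count(smoothing_window) || smoothing_window < 1)
    stop("'smoothing_window' must be a count >= 1")
  if (smoothing_window > n)
    stop("smoothing window longer than the signal")
  env <- Mod(analytic_signal(wave$samples))
  w <- as.integer(smoothing_window)
  if (w > 1) {
    nw <- n %/% w
    env <- colMeans(matrix(env[seq_len(nw * w)], nrow = w))
  }
  structure(
    list(values = env,
         sample_rate_effective = wave$sample_rate / w,
         smoothing_window = w),
    class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d values @ %.2f Hz effective (window %d)\n",
              length(x$values), x$sample_rate_effective, x$smoothing_window))
  invisible(x)
}

#' Segment an envelope into calls and pulses
#'
#' Thresholds the envelope at a fraction of its maximum to obtain a
#' presence/absence logical vector; sub-threshold gaps shorter than
#' `min_gap_pulse` are bridged (absorbing brief intra-pulse modulation dips),
#' remaining runs of presence are pulses, and consecutive pulses separated by
#' gaps shorter than `min_gap_call` are grouped into one call.
#'
#' Spans are half-open intervals `[onset, offset)` in seconds, with sample 1
#' starting at time 0.  Because the threshold is relative to the envelope
#' maximum, segmentation is invariant to a global amplitude scaling.
#'
#' @param env An [compute_envelope()] result.
#' @param threshold_fraction Threshold as a fraction of the envelope maximum,
#'   in (0, 1); default 0.1.
#' @param min_gap_pulse Gaps shorter than this (seconds) are bridged into the
#'   surrounding pulse; default 5 ms.
#' @param min_gap_call Gaps of at least `min_gap_pulse` but shorter than this
#'   (seconds) separate pulses within one call; longer gaps separate calls.
#'   Default 0.5 s.  Must exceed `min_gap_pulse`.
#' @return An object of class `call_segmentation`: `calls` (data frame of
#'   call spans), `pulses` (list, one data frame of pulse spans per call) and
#'   `threshold_used`.  A silent input yields zero calls, not an error.
#' @export
segment_calls <- function(env, threshold_fraction = 0.1,
                          min_gap_pulse = 0.005, min_gap_call = 0.5) {
  stopifnot(inherits(env, "envelope"))
  if (length(env$values) < 1) stop("empty envelope")
  if (!is_scalar(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop("'threshold_fraction' must lie in (0, 1)")
  if (min_gap_pulse < 0 || min_gap_call <= min_gap_pulse)
    stop("need min_gap_call > min_gap_pulse >= 0")
  rate <- env$sample_rate_effective
  peak <- max(env$values)
  mask <- if (peak > 0) env$values >= threshold_fraction * peak
          else rep(FALSE, length(env$values))
  empty <- structure(list(calls = data.frame(onset = numeric(0),
                                             offset = numeric(0)),
                          pulses = list(),
                          threshold_used = threshold_fraction),
                     class = "call_segmentation")
  if (!any(mask)) return(empty)

  # bridge short interior gaps
  runs0 <- logical_runs(!mask)
  for (i in seq_len(nrow(runs0))) {
    s <- runs0[i, 1]; e <- runs0[i, 2]
    if (s > 1 && e < length(mask) && (e - s + 1) / rate < min_gap_pulse)
      mask[s:e] <- TRUE
  }

  pruns <- logical_runs(mask)
  onsets <- (pruns[, 1] - 1) / rate
  offsets <- pruns[, 2] / rate
  np <- nrow(pruns)

  # group pulses into calls by inter-pulse gap
  grp <- cumsum(c(1, as.numeric(onsets[-1] - offsets[-np] >= min_gap_call)))
  calls <- data.frame(
    onset = tapply(onsets, grp, min),
    offset = tapply(offsets, grp, max),
    row.names = NULL)
  pulses <- lapply(split(data.frame(onset = onsets, offset = offsets), grp),
                   function(d) { rownames(d) <- NULL; d })
  names(pulses) <- NULL
  structure(list(calls = calls, pulses = pulses,
                 threshold_used = threshold_fraction),
            class = "call_segmentation")
}

#' @export
print.call_segmentation <- function(x, ...) {
  cat(sprintf("<call_segmentation> %d call(s), %s pulses (threshold %.2f)\n",
              nrow(x$calls),
              paste(vapply(x$pulses, nrow, 0L), collapse = "+"),
              x$threshold_used))
  invisible(x)
}
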