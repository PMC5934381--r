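#' Analyze recordings into a call-feature table
#'
#' Convenience wrapper chaining [compute_envelope()], [segment_calls()] and
#' [extract_features()] over one or more WAV files (or [waveform()]
#' objects), returning one row per detected call. When a covariate table is
#' supplied, the standard covariate corrections are fitted and applied: the
#' five temporal variables are regressed on water temperature and dominant
#' frequency on snout-vent length, each screened by its Pearson correlation
#' at `alpha`, and significant ones are adjusted to the covariate grand mean
#' ([correct_variable()]); corrected columns get a `_corr` suffix.
#'
#' @param x Character vector of WAV paths, a single [waveform()], or a list
#'   of waveforms (named, ideally).
#' @param threshold_fraction,min_gap_pulse,min_gap_call Segmentation
#'   parameters, see [segment_calls()].
#' @param smoothing_window Envelope smoothing for segmentation (samples;
#'   default 1 = raw Hilbert modulus).
#' @param covariates Optional data frame with columns `file`,
#'   `water_temperature` and/or `svl`, one row per recording.
#' @param alpha Screening significance level for corrections (default 0.05).
#' @return Data frame: `file`, `call_index`, `onset_s`, the seven call
#'   variables, and `_corr` columns when corrections were applied.
#' @export
analyze_recordings <- function(x, threshold_fraction = 0.1,
                               min_gap_pulse = 0.005, min_gap_call = 0.5,
                               smoothing_window = 1, covariates = NULL,
                               alpha = 0.05) {
  waves <- if (inherits(x, "waveform")) {
    list(wave = x)
  } else if (is.character(x)) {
    stats::setNames(lapply(x, read_wav), basename(x))
  } else if (is.list(x)) {
    if (is.null(names(x))) names(x) <- sprintf("wave%d", seq_along(x))
    x
  } else stop("'x' must be WAV paths, a waveform, or a list of waveforms")

  rows <- lapply(names(waves), function(nm) {
    w <- waves[[nm]]
    seg <- segment_calls(compute_envelope(w, smoothing_window),
                         threshold_fraction, min_gap_pulse, min_gap_call)
    feats <- extract_features(w, seg)
    if (nrow(feats) > 0) cbind(file = nm, feats) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)

  if (!is.null(covariates)) {
    temporal <- c("call_duration", "n_pulses", "mean_pulse_duration",
                  "mean_inter_pulse_interval", "pulse_rate",
                  "modulation_depth")
    pair <- function(vars, covname) {
      if (!covname %in% names(covariates)) return()
      xmeas <- covariates[[covname]][match(out$file, covariates$file)]
      for (v in vars) {
        ok <- is.finite(out[[v]]) & is.finite(xmeas)
        if (sum(ok) >= 3 && stats::sd(xmeas[ok]) > 0) {
          m <- fit_correction(out[[v]][ok], xmeas[ok], alpha)
          out[[paste0(v, "_corr")]] <<- correct_variable(out[[v]], m, xmeas)
        }
      }
    }
    pair(temporal, "water_temperature")
    pair("dominant_frequency", "svl")
  }
  out
}
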