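# Degradation table construction and the standardization / averaging /
# local-vs-foreign summary chain.

#' Measure attenuation and degradation metrics for one simulated transect
#'
#' For every configured distance and stimulus replicate, measures the
#' noise-corrected sound pressure level (power subtraction against the
#' channel's leading noise-only segment), the transmitted modulation depth
#' (400-point smoothed Hilbert envelope) and the spectral cross-correlation
#' against the same replicate recorded at the reference (closest) distance.
#' Replicates whose measured level is less than `snr_flag_db` above the
#' noise floor are flagged and their metrics set missing, mirroring the
#' exclusion of unusable field segments.
#'
#' @param rec A [simulate_transect()] result.
#' @param transect_id Label identifying the transect.
#' @param origin Label of the call origin (locality of the stimulus).
#' @param snr_flag_db Minimum level-above-noise in dB below which a replicate
#'   is flagged missing (default 3).
#' @param scc_window Window length for [mean_power_spectrum()] (default 440).
#' @param md_window Envelope smoothing for
#'   [transmitted_modulation_depth()] (default 400).
#' @return A long-format data frame (one row per distance x replicate):
#'   `transect`, `origin`, `distance`, `replicate`, `spl_db`,
#'   `modulation_depth`, `scc`, `flagged`.
#' @export
measure_transect <- function(rec, transect_id = "T1", origin = "unlabelled",
                             snr_flag_db = 3, scc_window = 440,
                             md_window = 400) {
  stopifnot(inherits(rec, "transect_recording"))
  cfg <- rec$config
  calib <- rec$calibration
  d_ref <- min(cfg$distances)
  fs <- rec$recordings[[1]]$sample_rate

  seg_of <- function(w, onset, dur) {
    i0 <- round(onset * fs) + 1
    i1 <- min(length(w$samples), round((onset + dur) * fs))
    waveform(w$samples[i0:i1], fs)
  }
  ref_name <- sprintf("%gm", d_ref)
  rows <- list()
  for (d in cfg$distances) {
    nm <- sprintf("%gm", d)
    w <- rec$recordings[[nm]]
    mk <- rec$markers[rec$markers$distance == d, ]
    noise_seg <- seg_of(w, mk$noise_onset_s[1], mk$noise_duration_s[1])
    for (j in seq_len(nrow(mk))) {
      call_seg <- seg_of(w, mk$onset_s[j], mk$duration_s[j])
      l_meas <- spl(call_seg, calib)
      l_noise <- spl(noise_seg, calib)
      flagged <- is.finite(l_noise) && (l_meas - l_noise) < snr_flag_db
      if (flagged) {
        spl_db <- md <- sc <- NA_real_
      } else {
        spl_db <- noise_corrected_spl(call_seg, noise_seg, calib)
        md <- transmitted_modulation_depth(call_seg, md_window)
        mk_ref <- rec$markers[rec$markers$distance == d_ref &
                                rec$markers$replicate == mk$replicate[j], ]
        ref_seg <- seg_of(rec$recordings[[ref_name]],
                          mk_ref$onset_s, mk_ref$duration_s)
        sc <- scc(mean_power_spectrum(ref_seg, scc_window),
                  mean_power_spectrum(call_seg, scc_window))
      }
      rows[[length(rows) + 1]] <- data.frame(
        transect = transect_id, origin = origin, distance = d,
        replicate = mk$replicate[j], spl_db = spl_db,
        modulation_depth = md, scc = sc, flagged = flagged)
    }
  }
  do.call(rbind, rows)
}

#' Standardize SPL and modulation depth within transect and origin
#'
#' Adds `sspl` and `smd` columns: each value divided by the highest value of
#' the same call origin within the same transect at the reference (shortest)
#' distance. SPL values are converted from dB to linear pressure amplitude
#' before the ratio is taken, so that under pure spherical spreading SSPL at
#' distance `d` equals `d_ref / d`. The reference maximum itself maps to
#' exactly 1. Spectral cross-correlation is not standardized (it already
#' references the shortest distance). Groups lacking usable reference-
#' distance rows are rejected: their standardized values are set missing
#' with a warning.
#'
#' @param table A degradation table from [measure_transect()] (rows may span
#'   several transects and origins).
#' @param reference_distance Reference distance in metres; default the
#'   smallest distance present.
#' @return The table with `sspl` and `smd` columns appended.
#' @export
standardize_by_origin <- function(table, reference_distance = NULL) {
  need <- c("transect", "origin", "distance", "spl_db", "modulation_depth")
  if (!all(need %in% names(table)))
    stop("table lacks columns: ", paste(setdiff(need, names(table)),
                                        collapse = ", "))
  if (is.null(reference_distance)) reference_distance <- min(table$distance)
  amp <- db_to_amp(table$spl_db)
  table$sspl <- NA_real_
  table$smd <- NA_real_
  for (g in split(seq_len(nrow(table)),
                  list(table$transect, table$origin), drop = TRUE)) {
    ref <- g[table$distance[g] == reference_distance]
    if (length(ref) == 0 || all(is.na(amp[ref]))) {
      warning(sprintf(
        "no usable reference-distance rows for transect '%s', origin '%s'",
        table$transect[g[1]], table$origin[g[1]]))
      next
    }
    table$sspl[g] <- amp[g] / max(amp[ref], na.rm = TRUE)
    md_ref_max <- suppressWarnings(max(table$modulation_depth[ref],
                                       na.rm = TRUE))
    if (is.finite(md_ref_max) && md_ref_max > 0)
      table$smd[g] <- table$modulation_depth[g] / md_ref_max
  }
  table
}

#' Average metrics over stimulus replicates
#'
#' Arithmetic mean of each metric over the replicates within each
#' (transect, origin, distance) cell. Flagged-missing replicates are
#' excluded from the mean; a cell whose replicates are all missing stays
#' missing.
#'
#' @param table A degradation table with a `replicate` column.
#' @return One row per (transect, origin, distance), metrics averaged.
#' @export
average_replicates <- function(table) {
  if (!"replicate" %in% names(table)) stop("no 'replicate' column")
  metrics <- intersect(c("spl_db", "modulation_depth", "scc", "sspl", "smd"),
                       names(table))
  key <- interaction(table$transect, table$origin, table$distance,
                     drop = TRUE, sep = "\r")
  first <- !duplicated(key)
  out <- table[first, c("transect", "origin", "distance")]
  for (m in metrics) {
    v <- tapply(table[[m]], key, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    })
    out[[m]] <- as.numeric(v[as.character(key[first])])
  }
  rownames(out) <- NULL
  out
}

#' Local-versus-foreign degradation contrast with permutation p-values
#'
#' For each metric present (`sspl`, `smd`, `scc`), computes the contrast
#' `mean(local) - mean(foreign)` per distance and overall, where "local"
#' rows are those whose call origin matches `locality`. Significance is
#' assessed by permuting call-origin labels within transects (equivalently,
#' re-drawing which origin counts as local in each transect) and counting
#' permuted contrasts at least as extreme in absolute value; the p-value is
#' `(1 + n_extreme) / (1 + n_permutations)`.
#'
#' @param table A standardized, replicate-averaged degradation table.
#' @param locality Label of the local call origin.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed; the same seed reproduces the report exactly.
#' @return A data frame with one row per metric x scope (`"overall"` or a
#'   distance): `metric`, `distance`, `mean_local`, `mean_foreign`,
#'   `contrast`, `p_value`, `n_permutations`.
#' @export
local_vs_foreign_summary <- function(table, locality, n_permutations = 10000,
                                     seed = 1) {
  origins <- unique(table$origin)
  if (!locality %in% origins)
    stop("locality '", locality, "' not present among call origins")
  if (length(origins) < 2)
    stop("need at least one foreign call origin")
  metrics <- intersect(c("sspl", "smd", "scc"), names(table))
  if (length(metrics) == 0) stop("no degradation metrics in table")

  transects <- unique(table$transect)
  by_transect <- lapply(transects, function(tr) which(table$transect == tr))
  origin_of <- table$origin
  distances <- sort(unique(table$distance))
  scopes <- c(list(overall = seq_len(nrow(table))),
              stats::setNames(lapply(distances,
                                     function(d) which(table$distance == d)),
                              distances))

  contrast_for <- function(local_mask) {
    vapply(metrics, function(m) {
      vapply(scopes, function(idx) {
        lv <- table[[m]][idx][local_mask[idx]]
        fv <- table[[m]][idx][!local_mask[idx]]
        mean(lv, na.rm = TRUE) - mean(fv, na.rm = TRUE)
      }, 0)
    }, numeric(length(scopes)))
  }

  obs_mask <- origin_of == locality
  obs <- contrast_for(obs_mask)

  extreme <- matrix(0, nrow = length(scopes), ncol = length(metrics))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_permutations)) {
      mask <- logical(nrow(table))
      for (ti in seq_along(transects)) {
        idx <- by_transect[[ti]]
        og <- unique(origin_of[idx])
        local_og <- og[sample.int(length(og), 1)]
        mask[idx] <- origin_of[idx] == local_og
      }
      perm <- contrast_for(mask)
      extreme <- extreme + (abs(perm) >= abs(obs) - 1e-12)
    }
  })
  pvals <- (1 + extreme) / (1 + n_permutations)

  mean_local <- vapply(metrics, function(m)
    vapply(scopes, function(idx)
      mean(table[[m]][idx][obs_mask[idx]], na.rm = TRUE), 0),
    numeric(length(scopes)))
  mean_foreign <- vapply(metrics, function(m)
    vapply(scopes, function(idx)
      mean(table[[m]][idx][!obs_mask[idx]], na.rm = TRUE), 0),
    numeric(length(scopes)))

  data.frame(
    metric = rep(metrics, each = length(scopes)),
    distance = rep(names(scopes), length(metrics)),
    mean_local = as.numeric(mean_local),
    mean_foreign = as.numeric(mean_foreign),
    contrast = as.numeric(obs),
    p_value = as.numeric(pvals),
    n_permutations = n_permutations,
    row.names = NULL)
}
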