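# End-to-end pipeline driver: configuration, synth -> simulate -> degrade ->
# summarize, manifest, and the fixture battery used by the test-suite.

#' Illustrative locality parameter sets
#'
#' Three made-up parameter sets spanning the plausible range of pulsed,
#' amplitude-modulated advertisement calls (carrier around 2-3 kHz, calls
#' around a second long, five intra-pulse modulations). These are
#' illustrative defaults for demos and tests, not measurements from any
#' field population; real analyses should supply their own per-locality
#' values via the config file.
#'
#' @return Named list of [call_parameters()] objects.
#' @export
demo_localities <- function() {
  list(
    north = call_parameters(dominant_frequency = 2200, n_pulses = 12,
                            pulse_duration = 0.040, inter_pulse_interval = 0.060,
                            modulation_depth = 95, n_intra_pulse_modulations = 5,
                            locality_label = "north"),
    central = call_parameters(dominant_frequency = 2700, n_pulses = 14,
                              pulse_duration = 0.035, inter_pulse_interval = 0.050,
                              modulation_depth = 90, n_intra_pulse_modulations = 5,
                              locality_label = "central"),
    south = call_parameters(dominant_frequency = 2100, n_pulses = 10,
                            pulse_duration = 0.050, inter_pulse_interval = 0.070,
                            modulation_depth = 60, n_intra_pulse_modulations = 5,
                            locality_label = "south"))
}

#' Read a pipeline configuration
#'
#' Configurations are flat, human-editable YAML documents with blocks
#' `localities` (per-locality call parameters), `sites` (where transects are
#' simulated; each site name must match a defined locality), `stimulus`,
#' `transect`, `analysis`, `summary`, plus top-level `seed`, `sample_rate`
#' and `write_audio`. See `system.file("extdata", "demo_config.yaml",
#' package = "callprop")` for a worked example.
#'
#' @param path Path to a YAML config file, or a list already in that shape.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$localities) || length(cfg$localities) == 0)
    stop("config defines no localities")
  if (is.null(cfg$sites) || length(cfg$sites) == 0)
    stop("config defines no sites")
  missing <- setdiff(names(cfg$sites), names(cfg$localities))
  if (length(missing) > 0)
    stop("site(s) reference undefined localities: ",
         paste(missing, collapse = ", "))
  if (is.null(cfg$seed))
    stop("config must carry a seed (stochastic stages are enabled)")
  cfg$sample_rate <- cfg$sample_rate %||% 44100
  cfg$write_audio <- cfg$write_audio %||% TRUE
  cfg$stimulus <- cfg$stimulus %||% list()
  cfg$transect <- cfg$transect %||% list()
  cfg$analysis <- cfg$analysis %||% list()
  cfg$summary <- cfg$summary %||% list()
  structure(cfg, class = c("pipeline_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_call_parameters <- function(lc, label) {
  call_parameters(
    dominant_frequency = lc$dominant_frequency,
    n_pulses = lc$n_pulses,
    pulse_duration = lc$pulse_duration,
    inter_pulse_interval = lc$inter_pulse_interval,
    modulation_depth = lc$modulation_depth,
    n_intra_pulse_modulations = lc$n_intra_pulse_modulations %||% 5,
    call_duration = lc$call_duration,
    pulse_rate = lc$pulse_rate,
    locality_label = label)
}

config_transect <- function(tc, seed) {
  ea <- tc$excess_attenuation
  if (!is.null(ea)) ea <- do.call(rbind, lapply(ea, as.data.frame))
  transect_config(
    distances = unlist(tc$distances %||% c(0.5, 2, 4, 8, 16)),
    reference_distance = tc$reference_distance %||% 0.5,
    source_level = tc$source_level %||% 90,
    excess_attenuation = ea,
    reverb_decay = tc$reverb_decay %||% 0,
    noise_level = tc$noise_level %||% -Inf,
    noise_lead = tc$noise_lead %||% 0.5,
    seed = seed)
}

#' Run the full synthesis-propagation-degradation pipeline
#'
#' Executes the four stages in order — stimulus synthesis per locality,
#' transect simulation per site x transect x call origin, degradation
#' measurement (standardized and replicate-averaged), and per-site
#' local-versus-foreign summaries — writing all tabular intermediates and a
#' run manifest to `outdir`. The run is fully reproducible from the config
#' and its seed: one top-level seed fans out deterministically to per-stage
#' child seeds.
#'
#' @param config A config list or YAML path (see [read_pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the run manifest (also written as `manifest.yaml`):
#'   tool version, config hash, seed, per-stage counts, output files and
#'   accumulated warnings.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  warn <- character(0)
  note <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  fs <- cfg$sample_rate
  spec <- stimulus_spec(
    n_replicates = cfg$stimulus$n_replicates %||% 5,
    inter_stimulus_interval = cfg$stimulus$inter_stimulus_interval %||% 6)

  # --- synth ---------------------------------------------------------------
  stimuli <- list()
  for (loc in names(cfg$localities)) {
    params <- config_call_parameters(cfg$localities[[loc]], loc)
    stimuli[[loc]] <- build_stimulus_train(synthesize_call(params, fs), spec)
    if (isTRUE(cfg$write_audio)) {
      f <- file.path(outdir, sprintf("stimulus_%s.wav", loc))
      write_wav(stimuli[[loc]], f)
      files <- c(files, f)
    }
  }
  note("synth", sprintf("%d stimuli built", length(stimuli)))

  # --- simulate + degrade ----------------------------------------------------
  tables <- list()
  sim_count <- 0
  for (site in names(cfg$sites)) {
    n_tr <- cfg$sites[[site]]$n_transects %||% 5
    for (tr in seq_len(n_tr)) {
      for (origin in names(stimuli)) {
        sim_count <- sim_count + 1
        tc <- config_transect(cfg$transect, child_seed(cfg$seed, sim_count))
        rec <- simulate_transect(stimuli[[origin]], tc)
        tid <- sprintf("%s_t%d", site, tr)
        if (isTRUE(cfg$write_audio)) {
          for (nm in names(rec$recordings)) {
            f <- file.path(outdir, sprintf("%s_%s_%s.wav", tid, origin, nm))
            write_wav(rec$recordings[[nm]], f)
            files <- c(files, f)
          }
          f <- file.path(outdir, sprintf("%s_%s_markers.csv", tid, origin))
          utils::write.csv(rec$markers, f, row.names = FALSE)
          files <- c(files, f)
        }
        tbl <- measure_transect(rec, transect_id = tid, origin = origin)
        tbl$site <- site
        tables[[length(tables) + 1]] <- tbl
      }
    }
  }
  note("simulate", sprintf("%d transect simulations", sim_count))

  raw <- do.call(rbind, tables)
  flagged_n <- sum(raw$flagged)
  if (flagged_n > 0)
    warn <- c(warn, sprintf("%d replicate segments flagged below SNR floor",
                            flagged_n))
  std <- do.call(rbind, lapply(split(raw, raw$site), standardize_by_origin))
  rownames(std) <- NULL
  f <- file.path(outdir, "degradation_table.csv")
  utils::write.csv(std, f, row.names = FALSE)
  files <- c(files, f)

  avg <- do.call(rbind, lapply(split(std, std$site), function(s) {
    a <- average_replicates(s)
    a$site <- s$site[1]
    a
  }))
  rownames(avg) <- NULL
  f <- file.path(outdir, "degradation_table_averaged.csv")
  utils::write.csv(avg, f, row.names = FALSE)
  files <- c(files, f)
  note("degrade", sprintf("%d rows measured, %d flagged", nrow(raw), flagged_n))

  # --- summarize -------------------------------------------------------------
  summaries <- lapply(names(cfg$sites), function(site) {
    s <- avg[avg$site == site, ]
    rep <- local_vs_foreign_summary(
      s, locality = site,
      n_permutations = cfg$summary$n_permutations %||% 10000,
      seed = child_seed(cfg$seed, 990000 + match(site, names(cfg$sites))))
    rep$site <- site
    rep
  })
  contrasts <- do.call(rbind, summaries)
  f <- file.path(outdir, "local_vs_foreign.csv")
  utils::write.csv(contrasts, f, row.names = FALSE)
  files <- c(files, f)
  note("summarize", sprintf("%d contrast rows", nrow(contrasts)))

  manifest <- list(
    tool = "callprop",
    version = as.character(utils::packageVersion("callprop")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    stages = list(synth = length(stimuli), simulate = sim_count,
                  degrade = nrow(raw), summarize = nrow(contrasts)),
    files = basename(files),
    warnings = warn)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

# Reproducible hash of a config: md5 of its canonical YAML serialization.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate the on-disk test-fixture battery
#'
#' Writes a small, fully synthetic fixture set: one clean stimulus WAV per
#' illustrative locality, one simulated transect per locality (five
#' distances each) with sidecar marker CSVs, a calibration-tone WAV per
#' transect (1 kHz at 94 dB SPL under that transect's calibration), and an
#' expected-features CSV whose values are computed arithmetically from the
#' generating parameters, independently of the analysis code.
#'
#' @param seed Integer seed for the noise realizations (clean stimuli do not
#'   depend on it).
#' @param outdir Writable output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
generate_fixtures <- function(seed, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("outdir not writable: ", outdir)
  locs <- demo_localities()
  fs <- 44100
  files <- character(0)
  expected <- list()
  for (i in seq_along(locs)) {
    loc <- names(locs)[i]
    p <- locs[[loc]]
    stim <- build_stimulus_train(synthesize_call(p, fs), stimulus_spec())
    f <- file.path(outdir, sprintf("stimulus_%s.wav", loc))
    write_wav(stim, f)
    files <- c(files, f)

    tc <- transect_config(noise_level = 45, reverb_decay = 0.005,
                          excess_attenuation = data.frame(
                            lower = 3000, upper = fs / 2, coef = 0.4),
                          seed = child_seed(seed, i))
    rec <- simulate_transect(stim, tc)
    for (nm in names(rec$recordings)) {
      f <- file.path(outdir, sprintf("t%d_%s_%s.wav", i, loc, nm))
      write_wav(rec$recordings[[nm]], f)
      files <- c(files, f)
    }
    f <- file.path(outdir, sprintf("t%d_%s_markers.csv", i, loc))
    utils::write.csv(rec$markers, f, row.names = FALSE)
    files <- c(files, f)

    # calibration tone at 94 dB SPL under this transect's calibration
    tone_amp <- rec$calibration$tone_rms_digital * sqrt(2)
    tone <- waveform(tone_amp * sin(2 * pi * 1000 * (0:(fs - 1)) / fs), fs)
    f <- file.path(outdir, sprintf("t%d_%s_caltone.wav", i, loc))
    write_wav(tone, f)
    files <- c(files, f)

    # expected features from construction arithmetic (analysis-independent)
    expected[[loc]] <- data.frame(
      locality = loc,
      call_duration = p$call_duration,
      n_pulses = p$n_pulses,
      mean_pulse_duration = p$pulse_duration,
      mean_inter_pulse_interval = p$inter_pulse_interval,
      pulse_rate = p$n_pulses / p$call_duration,
      modulation_depth = p$modulation_depth,
      dominant_frequency = p$dominant_frequency)
  }
  f <- file.path(outdir, "expected_features.csv")
  utils::write.csv(do.call(rbind, expected), f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
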