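# callprop

Synthesis, analysis and propagation modelling of pulsed, amplitude-modulated
anuran advertisement calls.

## What problem this solves

In sound-transmission experiments, synthetic advertisement calls built from
per-locality averages are broadcast in the field and re-recorded by a
transect of microphones (0.5, 2, 4, 8 and 16 m), to ask how habitat shapes
signal attenuation and degradation — for instance, whether a locality's own
call transmits better there than foreign calls (the acoustic adaptation
hypothesis). `callprop` implements the full measurement chain for workers in
bioacoustics and animal communication:

* **Stimulus synthesis** — multi-pulse calls with a sinusoidal carrier and a
  raised-cosine intra-pulse modulator (`k` envelope cycles per pulse, depth
  `d` in percent defined as `100·(max − min)/max` of the pulse envelope),
  assembled into replicate trains (default 5 replicates, 6-s
  inter-stimulus interval), exported as 16-bit/44.1-kHz WAV.
* **Call analysis** — Hilbert-envelope segmentation (relative amplitude
  threshold, gap bridging) and the seven standard call variables: call
  duration, pulse number, mean pulse duration, mean inter-pulse interval,
  pulse rate, modulation depth, dominant frequency; plus covariate
  correction to the grand mean, `Ycorr = Y − b·Xmeasured + b·Xmean`,
  screened by the Pearson correlation at α = 0.05.
* **Transect simulation** — a parametric stand-in for field transects:
  spherical spreading (`20·log10(d/d_ref)` dB, 6 dB per doubling), band-wise
  excess attenuation (dB/m, zero-phase), reverberant smearing, calibrated
  Gaussian background noise, with per-channel calibration constants and
  noise-only lead segments.
* **Degradation statistics** — SPL calibrated against a 1-kHz 94-dB-SPL RMS
  tone and noise-corrected by power subtraction; standardized sound
  pressure level (**SSPL**) and standardized modulation depth (**SMD**),
  each value divided by the highest reference-distance value of its
  transect × origin group; spectral cross-correlation (**SCC**), the
  zero-lag Pearson correlation of mean power spectra (440-point Hanning
  windows, 0% overlap: 100.227 Hz / 9.977 ms resolution) between the
  0.5-m recording and each farther distance; replicate averaging; and
  permutation-based local-versus-foreign contrasts.

## Worked example

```r
library(callprop)

params <- call_parameters(dominant_frequency = 2200, n_pulses = 12,
                          pulse_duration = 0.040, inter_pulse_interval = 0.060,
                          modulation_depth = 95, locality_label = "north")
call <- synthesize_call(params)
analyze_recordings(call)[, c("n_pulses", "call_duration", "pulse_rate",
                             "modulation_depth", "dominant_frequency")]
#>   n_pulses call_duration pulse_rate modulation_depth dominant_frequency
#> 1       12         1.139      10.53               95               2196
```

The analysis recovers the generating parameters: 12 pulses, the 1.14-s call
(12 × 40 ms + 11 × 60 ms), depth 95%, and the 2200-Hz carrier within one
FFT bin (10.8 Hz).

```r
stim <- build_stimulus_train(call, stimulus_spec(n_replicates = 5,
                                                 inter_stimulus_interval = 6))
cfg <- transect_config(noise_level = 45, reverb_decay = 0.005,
                       excess_attenuation = data.frame(lower = 3000,
                                                       upper = 22050,
                                                       coef = 0.4),
                       seed = 42)
rec <- simulate_transect(stim, cfg)
average_replicates(standardize_by_origin(measure_transect(rec, "t1", "north")))
#>   transect origin distance spl_db modulation_depth scc   sspl   smd
#> 1       t1  north      0.5   78.6             99.0   1 0.9999 1.000
#> 2       t1  north      2.0   66.5             95.9   1 0.2500 0.969
#> 3       t1  north      4.0   60.5             91.7   1 0.1250 0.926
#> 4       t1  north      8.0   54.5             83.9   1 0.0625 0.847
#> 5       t1  north     16.0   48.5             69.5   1 0.0314 0.703
```

SSPL follows the spherical-spreading amplitude law (`0.5/d`: 0.25, 0.125,
0.0625, ~0.031), SMD declines with distance as noise and reverberation fill
the inter-pulse gaps (temporal degradation), and SCC stays near 1 because
this 2.2-kHz call sits below the attenuated band (little spectral
degradation). `run_pipeline()` chains synthesis → simulation → measurement →
local-vs-foreign summaries for a whole multi-locality config
(see `inst/extdata/demo_config.yaml`) and writes the long-format tables plus
a manifest.

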