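---
title: "Measuring attenuation and degradation of pulsed advertisement calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring attenuation and degradation of pulsed advertisement calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callprop)
```

## The measurement problem

Many frogs advertise with trains of amplitude-modulated pulses. As such a
call propagates away from the caller it is attenuated (it gets quieter),
spectrally degraded (habitat filtering reshapes its spectrum) and temporally
degraded (reverberation and noise blur its amplitude modulation). Transmission
experiments quantify these three axes by broadcasting synthetic calls built
from per-locality averages and re-recording them along a transect of
microphones (here 0.5, 2, 4, 8 and 16 m), asking — among other things —
whether a locality's own ("local") call survives its habitat better than
"foreign" calls.

`callprop` implements that entire measurement chain: stimulus synthesis,
envelope-based call analysis, a parametric propagation simulator that stands
in for field transects, and the calibrated degradation statistics.

## Call model and synthesis

A call is `n_pulses` identical pulses separated by a fixed silent
inter-pulse interval. One pulse is a sinusoidal carrier at the dominant
frequency, shaped by a raised-cosine intra-pulse modulator

$$ e(t) = 1 - \frac{d}{100}\,\frac{1 - \cos(2\pi k t / T)}{2}, \qquad 0 \le t \le T, $$

with `T` the pulse duration, `k` the number of intra-pulse modulations
(five, the typical value in this kind of call) and `d` the modulation depth
in percent. This shape is chosen so that the standard depth measure,
$100\,(\max - \min)/\max$ of the pulse envelope, equals `d` by construction,
and so that the envelope starts and ends each pulse at its maximum, which
keeps threshold segmentation of pulse boundaries sharp. The carrier phase and
all timing are deterministic: the same parameters always give bit-identical
samples.

Two numerical choices are not dictated by the call model:

* **Gating.** Each pulse is gated by 2-ms cosine rise/fall ramps to avoid
  spectral splatter from rectangular onsets. Depth is therefore measured on
  the pulse *interior*, 2 ms in from each detected edge.
* **Onset placement.** Pulse onsets are placed by rounding each true onset
  time (`(j-1)(T + \mathrm{IPI})`) to the sample grid independently, rather
  than accumulating a rounded period, so timing error stays below one sample
  regardless of pulse count.

Playback stimuli repeat the call (default five replicates at a 6-s
inter-stimulus interval, the usual transmission-experiment protocol), with
replicate onsets annotated for downstream per-replicate measurement.

Peak amplitude defaults to 0.9 of full scale so that 16-bit PCM export never
clips.

## Envelope analysis and the seven call variables

The analysis path mirrors the classic automated routine: the envelope is the
modulus of the analytic signal (Hilbert transform), a relative amplitude
threshold (default 10% of the envelope maximum) produces a presence/absence
vector, runs of presence are pulses, and pulses separated by less than
`min_gap_call` (default 0.5 s) form one call. Two pragmatic parameters
replace the manual error correction of interactive workflows:

* `min_gap_pulse` (default 5 ms): sub-threshold dips shorter than this are
  bridged. Deep intra-pulse modulation (`d` near 100) legitimately drives
  the envelope below any fixed threshold for a fraction of each modulation
  cycle (for five cycles in a 20–80-ms pulse these dips last ~1–4 ms), and
  must not split a pulse. The default is safely above those dip lengths and
  safely below realistic inter-pulse intervals (tens of ms).
* the threshold itself is exposed; the default 0.1 trades onset accuracy
  (the crossing happens ~0.4 ms into a 2-ms ramp) against noise robustness.

From a segmentation the package measures the seven standard variables: call
duration, pulse number, mean pulse duration, mean inter-pulse interval
(missing for one-pulse calls), pulse rate (defined here as
`n_pulses / call_duration`; an inter-onset-interval definition would be an
alternative, but this one is stable for short calls), modulation depth of
the central pulse (`ceiling(n/2)` for even counts), and dominant frequency —
the spectral peak of the central pulse, Hann-windowed and zero-padded to at
least 4096 points (bin width 10.8 Hz at 44.1 kHz) so peak location does not
depend on pulse length.

Covariate correction follows the standard adjustment-to-the-grand-mean
equation `Ycorr = Y - b*Xmeasured + b*Xmean`, with the slope `b` from an
ordinary least-squares fit and the correction applied only when the Pearson
correlation between variable and covariate is significant at `alpha = 0.05`
(temporal variables against water temperature, dominant frequency against
snout-vent length). The correction is affine in `Y` with unit slope, so it
shifts but never rescales between-call differences.

## The propagation simulator

Field transects are replaced by a minimal forward model with one term per
measured degradation axis:

* **geometric spreading** — `20*log10(d/d_ref)` dB, the spherical-spreading
  law (6 dB per doubling of distance);
* **excess attenuation** — per-frequency-band gains of `-coef*(d - d_ref)`
  dB applied by a zero-phase piecewise spectral filter (zero-phase so pulse
  onsets are not shifted, which would bias temporal metrics);
* **reverberation** — convolution with a deterministic reverberation
  impulse response: a direct-path impulse followed by a diffuse reflection
  tail whose magnitude decays exponentially with time constant
  `reverb_decay` (truncated at six time constants). A naive all-positive
  exponential smoothing kernel would act as a low-pass filter of cutoff
  `1/(2*pi*decay)` — a few hertz — and silently annihilate a kilohertz
  carrier; modelling the reflections as a sign-varying tail smears the
  envelope (filling inter-pulse gaps and lowering measured modulation
  depth) while passing the carrier band. The kernel is normalized by its
  peak spectral magnitude, so no frequency is amplified and signal energy
  can never increase; the resulting fixed insertion loss is identical at
  all distances of a transect and cancels in the standardized metrics;
* **background noise** — stationary white Gaussian noise at a calibrated
  broadband level, seeded and reproducible.

It does not attempt ray tracing, ground effects, wind or vegetation
scattering; consequently, agreement of the metrics on simulated transects
demonstrates the correctness of the measurement chain, not the realism of
any particular habitat. Each simulated channel carries a shared calibration
constant chosen so the stimulus at the reference distance measures
`source_level` dB SPL (default 90 dB SPL at 0.5 m — playback levels in the
field are rig-dependent, and all downstream statistics are standardized, so
this is a free parameter). A noise-only lead segment (default 0.5 s) is
prepended to every channel to support noise correction, with its span
recorded in sidecar markers.

## Degradation statistics

All levels are calibrated against a 1-kHz, 94-dB-SPL RMS reference tone:
`SPL(x) = 94 + 20*log10(rms(x)/rms(tone))`.

* **Noise-corrected SPL.** Calls are measured embedded in noise, so the
  noise power measured on a contiguous noise-only segment is subtracted:
  `L = 10*log10(10^(Lmeas/10) - 10^(Lnoise/10))`. If the measured level is
  within 3 dB of the noise floor the replicate is flagged and excluded
  (missing, never zero) — the automated analogue of discarding visually
  unusable segments.
* **SSPL.** Within each transect and call origin, linear pressure amplitudes
  (`10^(SPL/20)`) are divided by the highest reference-distance (0.5 m)
  value, so the reference maximum is exactly 1 and, under pure spherical
  spreading, SSPL at distance `d` is `d_ref/d`. The division is done on
  amplitudes, not dB values: only then does the standardized quantity obey
  that law, and a global gain applied to a whole transect cancels.
* **SMD.** Modulation depth standardized the same way. The transmitted
  depth is measured on the 400-point-smoothed Hilbert envelope (0% overlap)
  of the replicate's pulse train, between the first and last half-maximum
  envelope values. Measuring across the train rather than within a single
  pulse is a deliberate choice: at a 9-ms smoothing scale the depth *within*
  a 20–50-ms pulse is dominated by the smoother, while the train-level
  depth responds monotonically to the gap-filling by reverberation and
  noise that the metric is meant to index.
* **SCC.** Mean power spectra over non-overlapping 440-point Hanning
  windows (100.227-Hz and 9.977-ms resolution at 44.1 kHz), correlated at
  zero lag (Pearson, linear power; a dB-scale option exists) between the
  reference recording and each farther distance, restricted by default to
  0–10 kHz where call energy lives. SCC is not standardized — it already
  references the shortest distance.

Replicate metrics are averaged within (transect, origin, distance), missing
values propagating as missing.

## Local-versus-foreign contrasts

The package summarizes origin effects descriptively: for each metric, the
contrast `mean(local) - mean(foreign)` per distance and overall, with a
permutation p-value obtained by re-drawing, independently within each
transect, which origin counts as local (equivalent to permuting origin
labels within transects) — `(1 + n_extreme)/(1 + B)` with two-sided
extremeness. Under a true null this p-value is uniform, which the test-suite
verifies by simulation. Mixed-effects modelling of the resulting tables
(random transect intercepts, REML, type-III tests) is intentionally out of
scope; the long-format CSV output is designed to drop straight into any
statistics package.

## What the simulations do and do not establish

The synthetic-data modules emulate the *structure* of the field data —
multi-pulse AM calls with five intra-pulse modulations, five-replicate
stimulus trains, five-microphone transects with calibration tones and
contiguous noise segments. They do not emulate habitat-specific filtering
shapes, non-stationary noise, playback-chain distortion, or microphone
directivity. Green tests therefore certify the measurement arithmetic and
its invariances (scale invariance of segmentation and depth, the
spreading law, calibration identities, reproducibility), not ecological
conclusions about any real locality.

Problem sizes used by the test-suite and the acceptance script were chosen
to exercise every code path at desk scale: 100 (suite) / 50 (script)
randomized parameter sets for the synthesis–analysis round trip, single
transects with two-replicate trains for the propagation laws, 200 simulated
null datasets at 199 permutations for p-value calibration, and a
two-locality demo pipeline (one transect, 199 permutations) for end-to-end
determinism.

## Known limitations

* The envelope threshold, smoothing and pulse-rate definitions are exposed
  defaults, not universal constants; recordings with strong low-frequency
  noise may need a band-pass before segmentation (not provided).
* Sub-bin dominant-frequency interpolation is not attempted; accuracy is one
  FFT bin (~10.8 Hz at the default padding).
* The simulator's excess attenuation is linear in distance per band;
  real habitats can be strongly non-linear over 16 m.
* `read_wav`/`write_wav` handle exactly the canonical field format
  (RIFF PCM, 16-bit, mono); other encodings are rejected rather than
  converted.
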