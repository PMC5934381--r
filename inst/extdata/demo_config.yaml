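# Demo pipeline configuration.
#
# The locality parameter sets below are illustrative values spanning the
# plausible range of pulsed amplitude-modulated advertisement calls; they are
# NOT measurements from any field population.  Replace them with your own
# per-locality averages for real analyses.
seed: 7
sample_rate: 44100
write_audio: false

localities:
  north:
    dominant_frequency: 2200
    n_pulses: 12
    pulse_duration: 0.040
    inter_pulse_interval: 0.060
    modulation_depth: 95
    n_intra_pulse_modulations: 5
  south:
    dominant_frequency: 2100
    n_pulses: 10
    pulse_duration: 0.050
    inter_pulse_interval: 0.070
    modulation_depth: 60
    n_intra_pulse_modulations: 5

# transects are simulated at these sites; each site name must be a defined
# locality (its stimulus is the "local" call there)
sites:
  north:
    n_transects: 2

stimulus:
  n_replicates: 5
  inter_stimulus_interval: 6

transect:
  distances: [0.5, 2, 4, 8, 16]
  reference_distance: 0.5
  source_level: 90        # dB SPL at the reference distance
  noise_level: 45         # broadband background, dB SPL
  reverb_decay: 0.005     # s
  excess_attenuation:
    - lower: 3000
      upper: 22050
      coef: 0.4           # dB per metre beyond the reference distance

analysis:
  threshold_fraction: 0.1
  min_gap_pulse: 0.005
  min_gap_call: 0.5

summary:
  n_permutations: 499
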