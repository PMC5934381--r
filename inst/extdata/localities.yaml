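# Illustrative per-locality call parameter sets (flat key -> value, one block
# per locality).  These are NOT field measurements; they are demo values with
# realistic orders of magnitude for a 2-3 kHz pulsed call with five
# intra-pulse modulations.  Supply your own values for real work.
north:
  dominant_frequency: 2200
  n_pulses: 12
  pulse_duration: 0.040
  inter_pulse_interval: 0.060
  modulation_depth: 95
  n_intra_pulse_modulations: 5
central:
  dominant_frequency: 2700
  n_pulses: 14
  pulse_duration: 0.035
  inter_pulse_interval: 0.050
  modulation_depth: 90
  n_intra_pulse_modulations: 5
south:
  dominant_frequency: 2100
  n_pulses: 10
  pulse_duration: 0.050
  inter_pulse_interval: 0.070
  modulation_depth: 60
  n_intra_pulse_modulations: 5
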