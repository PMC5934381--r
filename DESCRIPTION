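Package: callprop
Title: Synthesis, Analysis and Propagation Modelling of Pulsed Anuran Advertisement Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bioacoustic transmission studies of pulsed,
    amplitude-modulated anuran advertisement calls. Synthesizes calls and
    playback stimulus trains from per-locality parameter sets, segments
    recordings into calls and pulses by Hilbert-envelope thresholding and
    extracts seven standard call variables (call duration, pulse number,
    pulse duration, inter-pulse interval, pulse rate, modulation depth,
    dominant frequency) with covariate correction, simulates propagation
    transects under spherical spreading, band-wise excess attenuation,
    reverberation and background noise, and computes calibrated
    attenuation and degradation statistics: noise-corrected sound
    pressure level, standardized sound pressure level (SSPL),
    standardized modulation depth (SMD) and spectral cross-correlation
    (SCC), with replicate averaging and permutation-based local-versus-
    foreign contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
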