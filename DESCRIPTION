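Package: phasestim
Title: Closed-Loop Phase-Shifted Optogenetic Stimulation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-time simulator of a closed-loop optogenetic
    neuromodulation loop: an FIR band-pass/phase-shift controller converts a
    local field potential (LFP) into a light-stimulation command at a fixed
    1 ms tick, driving a synthetic stochastic neural oscillator through a
    model of the analog front end (level shifter, anti-aliasing filter,
    amplifier band-pass cascade, ADC). Includes an epoch scheduler for
    sequential or pseudorandomised stimulation conditions interspersed with
    no-stimulation controls, offline replay of recorded LFP files, and the
    phase-resolved spectral analysis (Welch power spectra, dominant-frequency
    detection, frequency-by-phase modulation maps) that demonstrates
    phase-dependent enhancement and suppression of neural oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    withr
Config/testthat/edition: 3
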