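Package: gyrostep
Title: Walking Detection and Step Counting from Smartphone Gyroscope Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects walking and counts steps from uniformly sampled 3-axis
    angular-velocity traces recorded by an unconstrained smartphone (arbitrary,
    possibly changing placement). A 64-sample sliding window is analysed in the
    frequency domain: the most sensitive gyroscope axis is selected by summed
    absolute angular velocity, its FFT amplitude spectrum is split into a
    walking band (0.6-2 Hz) and a sub-walking band, and a two-condition
    amplitude rule decides whether the holder is walking. Steps are counted
    indirectly as walking duration times cadence, with the cadence estimated by
    maximising a quartic polynomial interpolated through the five walking-band
    spectral samples and smoothed by an exponentially weighted moving average.
    Includes duration-based precision/recall and step-accuracy scoring, a
    labelled synthetic gait-trace generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
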