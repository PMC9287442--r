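Package: dgnovelty
Title: Dentate Gyrus Novelty Signals and CA3 Map Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a transient membrane-potential novelty signal in
    dentate gyrus granule cells and its downstream effect on hippocampal CA3.
    Provides a synthetic-data generator for in-vivo-like granule-cell membrane
    potential recordings with teleportation-locked depolarising transients,
    spike removal and teleportation-aligned averaging with nonparametric
    statistics, a bootstrap estimator of the increase in the fraction of
    spiking granule cells caused by the transient, and a continuous-attractor
    model of CA3 with clipped Hebbian couplings, dentate gyrus and entorhinal
    inputs, global inhibition, and a BCM-like plasticity rule that consolidates
    a novel spatial map.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
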