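Package: cacomm
Title: Transient Calcium-Signaling Communities and Hotspots in Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and statistical validation of transient multicellular
    calcium-signaling communities from single-cell fluorescence traces.
    Normalizes and binarizes GCaMP-like traces, links synchronously active
    neighboring cells into transient collective events, validates the spatial
    locality of events with a position-shuffle permutation test, detects
    recurrently active cell groups (hotspots) and validates them with an
    activity-matched trace-swap bootstrap, and quantifies hotspot-environment
    interaction and signal propagation speed. Includes a synthetic-data
    generator with planted cascades, hotspots and ground truth for end-to-end
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
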