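Package: cochleomap
Title: Three-Dimensional Cochlear Tonotopic Mapping and Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tonotopic analysis of 3D cochlear centerlines.
    Computes curvilinear arc lengths of basilar-membrane and spiral-ganglion
    centerlines, fits the mid-modiolar axis and measures unwrapped angular
    insertion depth from the round-window center, maps organ-of-Corti
    positions to characteristic frequency with the Greenwood
    frequency-position function, transfers frequencies to the spiral ganglion
    along traced peripheral dendrites, derives semitone rate-of-change
    profiles and octave-band segmentations, and evaluates innervation-density
    morphometry (cylinder-packing neuron counts, axon-density scaling, inner
    hair cell counts and innervation ratios). Includes a seeded parametric
    generator of synthetic cochlear geometries with ground truth so every
    stage is testable without imaging data, plus readers and writers for 3D
    Slicer markups fiducial files and labelled point CSVs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
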