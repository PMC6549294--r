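Package: morphofun
Title: Morphofunctional Profiling of Primary Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: High-content morphofunctional profiling of primary neuronal
    cultures. Segments nuclei, dendrites (Frangi vesselness) and pre-/post-
    synaptic puncta (difference-of-Gaussians) from multi-channel fluorescence
    fields, calls synapses by object overlap, extracts calcium-burst
    descriptors from time-lapse recordings, and integrates the per-field
    descriptors into a weighted connectivity score with culture-age
    classification. Ships a synthetic microscopy generator with full ground
    truth so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
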