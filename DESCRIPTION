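Package: driftclock
Title: Time Decoding and Drift Statistics for Longitudinal Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for days-scale longitudinal one-photon calcium
    imaging on linear tracks. Detects fluorescence events from dF/F traces with
    robust MAD thresholds and kinetic filters, registers cells across sessions
    by footprint correlation or centroid distance, computes place-field rate
    maps and spatial information with shuffle significance, quantifies
    representational drift (ensemble correlation decay, recurrence, divergence,
    monotonicity statistics), and infers when an episode was recorded with
    ordinal, within-environment, and across-environment correlation decoders
    backed by permutation and label-shuffle controls. Ships a synthetic-data
    generator with known ground truth (drifting rates, remapping, calcium
    kernels, jittered footprints) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
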