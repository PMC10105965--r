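Package: septodg
Title: Analysis of Septo-Hippocampal GABAergic Circuit Recordings
Version: 0.9.0
Authors@R:
    person("SeptoDG", "Developers", email = "septodg@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analyses used to
    characterise remodeling of the medial septum (MS) to dentate gyrus (DG)
    GABAergic circuit in Alzheimer's-model mice: fiber-photometry delta-F/F
    event detection, peri-event time-locking and MS-DG coupling, novel place
    recognition scoring, slice-electrophysiology metrics (sIPSC detection,
    opto-epoch contrasts, intrinsic membrane properties), and anatomical
    tracing quantification (connectivity ratio, co-localization, 3D projection
    density).  Every input the pipeline consumes can be generated synthetically
    with known ground truth, so all analyses are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
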