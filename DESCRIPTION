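Package: prosthesim
Title: Simulation and Analysis of Bidirectional Somatosensory Neuroprosthesis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying implanted bidirectional sensorimotor interfaces:
    synthetic intramuscular electromyography (EMG) and percept-report generation,
    waveform-length and mean-absolute-value feature extraction, channel-quality and
    crosstalk classification, spectral statistics for nerve-stimulation artifact
    detection, psychophysical threshold search with Shannon charge-safety limits,
    percept location stability via Jaccard similarity, longitudinal trend statistics,
    a proportional three degree-of-freedom neural-network myoelectric controller,
    and a virtual posture-matching evaluation environment with time-to-target and
    path-efficiency metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
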