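Package: fightphys
Title: Exercise Intensity and Capture-Stress Physiology of Longline-Caught
    Sharks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies exercise intensity of longline-captured sharks from
    1-Hz tri-axial accelerometer traces (vectorial-sum signal, windowed
    amplitude and cycle features, per-individual k-means with amplitude and
    cycle cutoff rules), derives exercise metrics such as the proportion of
    the capture event spent at low intensity and mean fight intensity, and
    relates blood-based physiological endpoints (pH, lactate, glucose,
    haematocrit, plasma ions) to exercise and environmental covariates with
    linear models and posterior-simulation confidence intervals. Ships a
    seeded synthetic capture-event and blood-panel generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
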