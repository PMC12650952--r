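Package: digitalchip
Title: Digital Microchamber Assay Simulation and Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for femtoliter-microchamber digital nucleic-acid assays:
    a synthetic two-channel chip image generator with per-chamber ground
    truth (Poisson single-molecule loading, sigmoidal amplification onset,
    shot and read noise, diffuse autofluorescent artifacts), microchamber
    detection in the reference channel, per-chamber mean intensity and
    radius-of-gyration features, two-stage positive/negative classification
    with Gaussian-fit negative-control thresholds, Poisson-partition
    absolute concentration estimation, and detection/quantification-time
    metrics for isothermal amplification time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
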