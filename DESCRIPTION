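Package: darelease
Title: Quantification of Evoked Dopamine Release from NIR Nanosensor Fluorescence Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for electrically evoked dopamine release imaged
    with near-infrared fluorescent single-walled carbon nanotube nanosensors.
    Computes per-pixel baselines and dF/F0 stacks from time-lapse movies,
    detects and filters dopamine-release hotspots, summarizes hotspot
    statistics per field of view, fits Langmuir sensor calibration curves and
    exponential clearance kinetics, and runs group comparisons. Includes a
    seeded synthetic-movie generator reproducing the statistical structure of
    control and GBA1 Parkinson's disease recordings so that every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
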