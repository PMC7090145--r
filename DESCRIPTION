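Package: camphen
Title: Phenotyping the Salt-Induced C3-to-CAM Transition in Ice Plant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for tracking the salt-induced transition
    from C3 to crassulacean acid metabolism (CAM) photosynthesis in
    Mesembryanthemum crystallinum. Provides image-based leaf-area
    measurement with in-frame 1 cm2 reference calibration, piecewise
    exponential growth-curve fitting with a treatment breakpoint, diel
    gas-exchange summarisation and detection of the nocturnal-assimilation
    onset of CAM, stomatal aperture statistics and day/night inversion
    detection, physiological indices (relative water content, leaf
    succulence, malondialdehyde content), per-day two-group comparisons
    with star annotation, and a seeded synthetic-data generator that
    emulates the study conditions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
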