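Package: as4dpm
Title: Diaphragm-Corrected 4D-CBCT Prediction Models for Target Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building marker-less target-position prediction
    models for respiratory motion management in radiotherapy. Extracts
    diaphragm (Amsterdam Shroud) waveforms from rotational kV projection
    image stacks, reconstructs short-arc 4D-CBCT target waveforms by
    8-phase sorting, corrects their amplitude and phase with the diaphragm
    signal (global percentile matching and sliding-window local matching),
    and fits quadratic position-velocity surrogate regression models.
    Includes a synthetic acquisition simulator (breathing traces, infrared
    surrogate markers, fiducial trajectories, projection images) providing
    ground truth for closed-loop evaluation, orthogonal-imager projection
    geometry with triangulation, and scenario-based prediction-error
    evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
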