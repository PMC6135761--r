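Package: fscvr
Title: Analysis of Chronic Fast-Scan Cyclic Voltammetry Dopamine Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and chemometric analysis of fast-scan cyclic
    voltammetry (FSCV) recordings from chronically implanted carbon-fiber
    microsensors. Provides triangular-waveform and scan-session data
    structures, background subtraction and color-plot assembly,
    principal-component regression calibration of dopamine against pH
    interference, sensor performance metrics (sensitivity, noise, limit of
    detection, functionality classification, implant geometry and
    mechanics), evoked dopamine transient kinetics, longitudinal stability
    statistics, and radial fluorescence-intensity profiling of implant
    tracks in histology images. A synthetic-data module generates
    flow-cell calibrations, evoked transients, sensor-fault sessions and
    implant-halo images with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
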