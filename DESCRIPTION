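Package: ewi3d
Title: Single-Heartbeat 3D Electromechanical Wave Imaging at High Volume Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for high-volume-rate 3D
    echocardiography with a 2D matrix array. Implements diverging-wave
    coherent-compounded delay-and-sum beamforming onto a pyramidal scan grid,
    inter-volume axial displacement estimation by 1-D normalized
    cross-correlation of beamformed RF signals, axial strain via a
    Savitzky-Golay least-squares gradient, electromechanical activation
    (isochrone) mapping from the onset of longitudinal shortening, and
    chamber-resolved end-systolic global longitudinal strain split at the
    atrio-ventricular junction. A point-scatterer phantom of a contracting
    heart with a prescribed activation wave provides known-truth channel data
    so every stage is testable without patient recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
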