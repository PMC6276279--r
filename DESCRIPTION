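Package: credkit
Title: Continuous-Rotation Electron Diffraction Acquisition Modelling,
    Screening and Export
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline computational core of a semi-automated continuous-rotation
    electron diffraction (cRED) and serial electron diffraction (SerialED)
    workflow. Provides Timepix detector-frame geometry correction (512x512 to
    516x516 module-gap expansion, cross masking, flatfield), primary-beam
    centre estimation, elliptical lens-distortion fitting and correction
    tables, defocus-tracking acquisition schedules with frame-exclusion
    bookkeeping, a convolutional neural network for diffraction-pattern
    screening with isolated-crystal selection, SMV/TIFF/MRC writers and
    XDS/DIALS/REDp instruction-file generation, per-frame intensity-scale
    quality control, and a rotating-crystal simulator that produces
    ground-truth test data without a microscope.
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
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
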