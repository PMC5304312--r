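Package: tonopulse
Title: Cardiac-Phase Dependence of Air-Puff Tonometry Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the cardiac (blood-pulsation) phase
    modulates intraocular pressure readings obtained with air-puff tonometry.
    The package extracts the anterior corneal contour from high-speed
    Scheimpflug-like image sequences, decomposes its motion into resting
    shape, whole-eye response and corneal reaction, measures deformation
    features (applanation times, maximum deformation, high-frequency corneal
    vibration), determines the pulse phase at the measurement trigger from a
    pulse-oximeter trace and bins it to a 30-degree grid, and runs a
    phase-shift Pearson correlation scan to locate the phase lag between the
    finger pulse and the intraocular pressure maximum.  A synthetic-data
    module generates pulse traces, pressure readings and rendered corneal
    cross-section image sequences with fully known ground truth, so the whole
    pipeline is testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
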