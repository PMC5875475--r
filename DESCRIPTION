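Package: ctssp
Title: Slice Sensitivity Profile Measurement for Helical CT Quality Assurance
Version: 0.1.0
Authors@R: person("QA", "Physics Tools", role = c("aut", "cre"),
    email = "qa-physics@example.org")
Description: Measures the slice sensitivity profile (SSP) of a helical CT
    scanner from an overlapping-slice image series of a point-response
    phantom (bead or thin disc). Reads single-frame CT DICOM series with
    rescale slope/intercept applied, builds background-corrected and
    normalized SSP curves from region-of-interest statistics (mean or
    maximum), and estimates the effective slice thickness as the full width
    at half maximum by linear interpolation (left-based, right-based,
    two-sided) or Gaussian curve fitting. Includes accuracy and precision
    statistics against manufacturer specifications (percent error, one- and
    two-sample z-tests), a synthetic phantom-series generator with known
    ground-truth SSP for end-to-end validation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
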