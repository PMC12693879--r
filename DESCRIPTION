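Package: ctiq
Title: Task-Based CT Image Quality Analysis with a Synthetic Catphan-Style Phantom
Version: 0.1.0
Authors@R: person("QA", "Physics", email = "qa.physics@example.org", role = c("aut", "cre"))
Description: Tools for task-based image quality analysis of axial CT phantom
    acquisitions in the style of AAPM TG-233: uniformity index and integral
    non-uniformity, slice thickness from 23-degree tilted wire ramps, Michelson
    contrast with CNR/SNR, histogram statistics, insert CT numbers and
    Hounsfield-unit linearity against linear attenuation coefficients, 2D/radial
    noise power spectrum with second-order polynomial detrending, target
    transfer function from circular inserts via ESF/LSF analysis, and the
    non-prewhitening detectability index for a circular task. Includes a
    synthetic Catphan-style phantom simulator (sensitometry, uniformity and
    low-contrast modules) with configurable Gaussian blur, stationary
    correlated noise of known power spectrum and radial cupping/capping
    fields, so that every metric is verifiable by parameter recovery against
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
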