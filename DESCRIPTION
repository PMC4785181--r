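Package: vwtsim
Title: Simulation and Analysis of Mouse Visual Perceptual Learning in the Visual Water Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mouse observers performing two-alternative forced-choice
    (2AFC) visual water task experiments and analyses the resulting behavior the
    way visual psychophysics studies do. Provides a synthetic-observer model
    (logistic psychometric function on log stimulus, saturating perceptual
    learning driven by near-threshold trials, interocular and cross-task
    transfer), the adaptive threshold-assessment procedure (descending and
    ascending staircases with 4-in-a-row or 7-of-10 criterion testing),
    frequency-of-seeing curves with 70-percent-correct threshold interpolation,
    contrast sensitivity functions, learning and transfer statistics (percent
    improvement, post/pre ratio, retention coefficient, transfer index, sucrose
    preference, dendritic spine density), and an intrinsic-signal optical
    imaging toolchain (synthetic cortical frame stacks, Fourier retinotopy,
    delta-R/R single-condition maps, circular smoothing, ROI spatial-frequency
    tuning, and cut-off spatial frequency by zero-crossing of a linear fit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
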