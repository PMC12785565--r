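Package: copagree
Title: Agreement Analysis of Textile-Sensor and Force-Platform
    Center-of-Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to validate wearable plantar-pressure sensor arrays
    against a laboratory force platform for center-of-pressure (CoP)
    measurement. Reconstructs CoP trajectories from six-channel textile
    sensor conductances by weighted vector summation, resamples and
    lag-aligns paired sock/platform waveforms, and quantifies agreement
    per waveform pair with root-mean-square error (absolute and
    quantile-range normalized), Bland-Altman limits of agreement, and
    Lin's concordance correlation coefficient with Fisher-transform
    confidence intervals. Includes a seeded simulator of squat-exercise
    CoP recordings (periodic squat trajectories, per-application sensor
    sensitivity and placement variability, platform placement offsets
    and side-step baseline shifts) so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
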