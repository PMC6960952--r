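Package: gaitevents
Title: Gait Event Detection from Foot-Mounted Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the four basic gait events (heel strike, toe strike,
    heel off, toe off) from tri-axial accelerometer recordings taken at the
    heel and toe during continuous walking. Raw accelerations are denoised
    with a wavelet modulus-maxima criterion, the gravity component is removed
    by whole-record mean subtraction, stance and swing phases are segmented by
    thresholding the smoothed jerk magnitude, vertical displacement is
    recovered by frequency-domain double integration with wavelet removal of
    the integration trend, and events are located at displacement troughs
    that drop or rise sharply. Includes a synthetic treadmill-gait generator
    with exact ground-truth event times, per-event error statistics and
    Bland-Altman agreement analysis, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
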