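Package: gaitdtw
Title: Locomotion Recognition from Lower-Back IMU Signals by Dynamic Time
    Warping Template Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-layer template-matching recognition of walking,
    ascending-stairs and descending-stairs episodes in six-axis inertial
    measurement unit (IMU) recordings from a lower-back (L5) sensor.  Builds
    per-activity, per-axis stride reference templates by dynamic time warping
    (DTW) barycenter averaging, matches them against continuous recordings
    with a sliding window refined by warping-path stretch analysis, converts
    accumulated distances to per-frame probabilities with per-axis
    thresholds, combines axes into a per-frame activity label, and evaluates
    recognition against frame-level gold-standard labels.  Includes a seeded
    synthetic IMU signal generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
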