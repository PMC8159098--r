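Package: stridelen
Title: Stride Length Estimation from Inertial Sensors and Optical Marker Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating acceleration-based stride and
    step length estimation models for pedestrian dead reckoning. Implements
    the full derivation pipeline from optical marker trajectories: signal
    conditioning (zero-phase Butterworth filtering, spline gap filling,
    linear resampling, wavelet denoising), numerical kinematics, gait event
    detection from heel displacement and acceleration peaks, a 28-parameter
    per-stride feature matrix, principal component regression with variance
    inflation factor screening, and selection of an acceleration-magnitude
    -range power-law model. Provides that model alongside four published
    comparator models (Weinberg, Kim, Zijlstra-Hof, Tian), least-squares
    constant tuning with personalized and universal scopes, stride-level and
    walked-distance evaluation metrics, and a seeded treadmill gait
    simulator with per-stride ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
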