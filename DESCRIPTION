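Package: echogaze
Title: Ultrasound Time-of-Flight Gaze Estimation on a Synthetic Acoustic Bench
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Physics-based emulation of an airborne-ultrasound eye-tracking
    bench and the downstream gaze-estimation analysis. A sphere-on-sphere
    model eye behind a parametric occluder is probed by directional
    megahertz transducers on a ring; acoustic rays with specular
    reflection, air attenuation and cosine-type transducer directivity
    yield per-receiver arrival times and weights, which are rendered into
    digitized tone-burst traces with session-to-session variability.
    Time-of-flight and peak-amplitude features are extracted by group
    averaging, Butterworth band-pass filtering and windowed peak
    detection, and gaze is regressed per axis with gradient-boosted
    regression trees against a linear baseline, reporting cross-validated
    RMSE, adjusted R-squared, epsilon-ball sensitivity curves, feature
    importances and per-pose error maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
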