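Package: gaitdmo
Title: Multi-Sensor Gait Event Detection, Stride Trajectories and Digital
    Mobility Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of synchronized wearable gait recordings:
    detection of initial and final foot contacts from pressure insoles and
    foot-mounted inertial units, event fusion, zero-velocity-update stride
    trajectory estimation with a Madgwick orientation filter and
    direct-reverse integration, walking-bout assembly and per-bout digital
    mobility outcomes (cadence, stride length, walking speed, stance time).
    Includes a marker-based stereophotogrammetric reference pipeline,
    agreement statistics (error summaries, ICC(2,1) with confidence
    intervals, sample-size planning), sensor noise characterization via
    Allan deviation, and a synthetic multi-sensor recording simulator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
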