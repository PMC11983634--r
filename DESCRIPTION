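Package: spotspray
Title: Target Spraying Decision and Hysteresis Control Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and control library for camera-guided spot spraying of
    weeds in tillering-stage wheat. Converts moving detection boxes into
    per-nozzle solenoid open/close commands: a grid decision algorithm maps
    boxes onto ten nozzle lanes and merges targets closer than the valve's
    minimum respondable spacing, and a hysteresis-compensation algorithm
    schedules valve actions by integrating discrete 10 Hz speed feedback with
    the composite trapezoidal rule to cancel processing, valve and droplet
    delays. Includes a synthetic belt-scene generator, a closed-loop bench
    simulator with virtual water-sensitive paper, and evaluation metrics
    (recognition, spraying and hit rates, coverage, targeting error).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
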