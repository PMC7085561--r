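Package: msft
Title: Sensor-Based Senior Fitness Test Scoring and Method-Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a smartphone-based Senior Fitness
    Test (SFT) workflow for older adults. Provides a gravity-sensor trace
    model with CSV input/output, a seeded simulator of gravity-vector traces
    with known ground-truth repetition counts, hysteresis state-machine
    repetition detectors for the sensor-based items (30-second chair stand,
    30-second arm curl, 2-minute step in place), normative-band scoring of
    full six-item SFT sessions, method-agreement statistics (intraclass
    correlation coefficients with F-based confidence intervals, Cronbach's
    alpha, Bland-Altman limits of agreement), System Usability Scale scoring,
    a file-backed session record store, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
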