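Package: actirhythm
Title: Circadian Actigraphy Analysis for Long-Term Activity and Body
    Temperature Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term rodent actigraphy recorded in
    fixed 5-minute bins (activity counts plus body temperature, as produced
    by implantable accelerometer tags). Models light-dark schedules and
    zeitgeber time, detects per-day activity phase markers (onset, offset,
    midpoint, peak) from crossings of short and long moving averages,
    estimates the free-running circadian period in constant darkness by FFT
    with sub-bin peak interpolation, profiles activity and temperature
    responses to light transitions, and applies the matched group statistics
    (pooled-variance t-test, exact enumeration Mann-Whitney U, Holm
    correction). Includes a seeded synthetic cohort generator so every stage
    is testable without animal data.
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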