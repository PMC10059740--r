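Package: feversurv
Title: Fever Surveillance from Continuous Infrared Doorway Recordings
Version: 0.1.0
Authors@R:
    person("feversurv", "maintainers", email = "feversurv@example.org",
           role = c("aut", "cre"))
Description: Tools for syndromic fever surveillance with a fixed infrared
    camera watching a doorway. Simulates continuous 9 Hz temperature
    recordings of passers-by (non-homogeneous Poisson arrivals, trapezoidal
    thermal signatures, sensor noise, hot-object confounders), identifies
    individual persons in the stream by temperature-time identification
    (threshold runs, gap merging, duration and plausibility filters),
    emulates alarm-driven single-frame capture with a front/back-of-head
    oracle, aggregates detections into daily and weekly fever statistics
    (counts, fever fraction, skewness), and correlates them with a weekly
    acute-respiratory-infection incidence series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
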