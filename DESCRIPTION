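Package: apistrack
Title: Escape, Velocity and Attractance Scoring for Automated Aversive
    Conditioning of Walking Honey Bees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for aversive olfactory conditioning of
    freely walking honey bees in a 1-D shuttle chamber monitored by a photo
    sensor array. Implements escape detection (midline crossing without
    return during a stimulus window), signed walking velocity from a cubic
    spline through dwell-collapsed position samples, and an Attractance
    Index obtained by trapezoid integration of the position trace, signed by
    the odor-injection side and normalized over the tested population.
    Includes the inferential layer used with such data (exact binomial
    rates, proportion and McNemar tests, bootstrapped rank correlations,
    cluster-bootstrap group comparisons, observer concordance), a calibrated
    agent-based simulator of bee behavior in the chamber, plain-text trace
    and event log readers and writers, and an end-to-end simulate, score,
    analyse, report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
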