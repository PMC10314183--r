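Package: flicrhythm
Title: Feeding-Rhythm Analysis for FLIC Capacitance Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scriptable pipeline for circadian feeding-rhythm analysis of
    Drosophila Fly Liquid-food Interaction Counter (FLIC) recordings: reads
    raw monitor CSV files, removes slow sensor drift by running-median or
    asymmetric-least-squares baselining, calls feeding events with the
    four-parameter FLIC criterion (feeding minimum, feeding threshold,
    consecutive licks, gap), summarises events into binned series, daily
    profiles, day/night splits and group statistics with Tukey-fence outlier
    flagging, and estimates free-running period and rhythm strength per well
    with an autocorrelation periodogram under constant darkness. Includes a
    synthetic-signal simulator with ground-truth feeding bouts so every stage
    can be validated without hardware data, and a command-line entry point
    driving the full pipeline from a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
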