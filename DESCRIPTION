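Package: dgrtools
Title: Dynamic Glucose Region Analysis for CGM Performance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterization of comparator (reference) blood glucose data
    collected during clinical performance studies of continuous glucose
    monitoring (CGM) systems. Implements rate-of-change (RoC) pairing of
    frequent-sampling-period comparator measurements, classification of
    RoC-BG pairs into the five regions of the dynamic glucose region (DGR)
    plot, checking of the recommended comparator data distribution (at
    least 7.5% of pairs in each critical region, at most 70% neutral), a
    deterministic elliptical-distance procedure that eliminates the least
    critical neutral pairs until the distribution requirements are met,
    detection and qualification of hypo- and hyperglycemic episodes in CGM
    traces with ambulatory-glucose-profile style aligned summaries, a
    synthetic-data generator emulating in-clinic target glucose profile
    sessions and free-living seven-point capillary testing, DGR plot
    rendering, and machine-readable study reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
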