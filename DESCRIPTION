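Package: telogel
Title: Terminal Restriction Fragment Telomere Length Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies telomere DNA length from terminal restriction
    fragment (TRF) Southern blots. Extracts lane intensity profiles from
    gel or phosphorimager images, refines molecular-weight ladder peaks,
    fits a two-segment log2-linear pixel-to-size calibration with a
    continuity-based switch point in the 8-10 kb range, converts telomere
    smears into size-normalized length distributions (correcting probe
    hybridization bias), and summarizes each lane as mean, median,
    quartile and interquartile telomere length. Includes cohort-level
    statistics (regression model families with AIC selection, all-subsets
    commonality analysis of R-squared, Benjamini-Hochberg adjusted
    correlation matrices), simulators for gels, smear lanes and cohorts
    with known ground truth, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
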