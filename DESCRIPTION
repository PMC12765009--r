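Package: vocalid
Title: Vocal Individuality Metrics for Bioacoustic Call Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies individual identity information in animal
    vocalisations from tables of call features (evenly resampled
    peak-frequency contours plus call duration). Implements Beecher's
    information statistic (HS) from per-component ANOVA decompositions,
    leave-one-out linear-discriminant discrimination scores (DS) and the
    index of vocal stereotypy (IVS), within- and between-individual
    acoustic distances (WID, BID), and probabilistic acoustic-niche
    overlap between individuals under a Bayesian multivariate-normal
    model. Includes readers for flat and Raven-selection-table call
    files, Wilcoxon rank-sum comparisons of per-individual metrics
    between density conditions, and a hierarchical Gaussian call
    simulator with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
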