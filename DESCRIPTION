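Package: fictloc
Title: Fictive Locomotion Rhythm, Interneuron Distribution and Neonatal
    Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of spinal locomotor circuits.
    Converts multi-channel ventral-root recordings into discharge envelopes,
    detects locomotor bursts and extracts cycle periods, computes circular
    phase statistics and cross-correlation rhythm strength for root pairs,
    characterizes cycle-frequency mode structure with kernel density
    estimation and two-sample Kolmogorov-Smirnov comparisons, normalizes
    interneuron soma positions into fractional spinal-cord coordinates and
    compares groups with a two-sample Hotelling's T-squared test, and scores
    neonatal swimming alternation and vestibulospinal paw-displacement
    measurements. Seeded synthetic-data generators reproduce the statistical
    structure every stage assumes, so the full pipeline is testable without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
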