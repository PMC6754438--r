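Package: ttmkit
Title: Triple Transient Measurement Analysis for Cardiomyocyte Drug Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes simultaneously recorded action-potential, calcium and
    contraction fluorescence signals of paced human induced pluripotent stem
    cell derived cardiomyocytes (hiPSC-CMs) into ten kinetic parameters, and
    classifies the contractile mechanism of action (MOA) of a drug with a
    hypothesis-table probability-score algorithm referenced to vehicle
    control measurements. Includes demultiplexing of interleaved
    three-channel frame stacks, ratiometric motion-artifact correction,
    pseudo-ratio dF/F normalization, pacing-aware event averaging, kinetic
    quantification (APD30/APD90, triangulation, calcium and contraction
    timing), vehicle-referenced Gaussian probability scoring with six MOA
    hypotheses, channel-subset ablation scoring, and a fully seeded
    synthetic-data simulator so that every pipeline stage is testable
    without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
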