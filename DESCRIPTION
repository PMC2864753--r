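Package: ferrolimit
Title: Integrative Transcriptome and Proteome Analysis of Bacterial Iron Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the iron-limitation response of marine
    bacteria such as 'Candidatus' Pelagibacter ubique from paired microarray
    and label-free LC-MS proteomics data. Implements chip normalization,
    replicate-averaged fold-change calling with Student t-tests, a modified
    radial-coordinate (RadViz) expression layout with cluster assignment, an
    accurate-mass-and-time (AMT) tag quantitation procedure (ppm/NET feature
    matching, technical-replicate presence filtering, minus-versus-average
    regression normalization, variability and F-score filters, protein
    log-ratio rollup with Fisher-combined significance), and
    transcript-protein decoupling summaries. A seeded synthetic-data
    generator emulates the six-culture, three-timepoint study design with
    planted expression programs for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
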