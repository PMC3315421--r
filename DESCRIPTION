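Package: regenexpr
Title: Expression and Outcome Analysis for CNS-Injury Regeneration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analyses used in invertebrate
    CNS-injury regeneration studies: efficiency-corrected qPCR relative
    quantification via Ct-Ct regression (standard-curve efficiency
    estimation, paired-Ct fits, intercept-based expression ratios, and
    time-course fold changes), a one-color microarray differential
    expression pipeline (75th-percentile normalization, log2 transform,
    replicate-probe median collapse, per-gene Student t-tests,
    significance and fold-change filters, hierarchical clustering for
    heat-map ordering), and outcome statistics (neurite net growth,
    one-way ANOVA from raw data or from printed mean/SEM/n summaries,
    Holm-Sidak post hoc adjustment, locomotion summaries). Includes
    synthetic-data generators with known ground truth for
    parameter-recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
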