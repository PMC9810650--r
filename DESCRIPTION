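Package: rxcov
Title: Immunoassay Analyte Fidelity via the Ratio of Cross Coefficients of Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes rxCOV, a fidelity metric that decides whether the
    differential expression of an analyte between two sample groups is
    distinguishable from assay-associated noise measured on repeat aliquots.
    Provides moment and robust (median/IQR) estimators, paired and unpaired
    differential-expression modes, per-analyte batch screening for multiplexed
    immunoassays (e.g. multiplexed ELISA panels), a Monte-Carlo noise-injection
    simulator with gamma-scans, zero-crossing fidelity thresholds,
    spurious-significance detection, replicate-averaging sufficiency analysis,
    a paired-vs-unpaired sensitivity grid, and a command-line interface for
    reproducible runs on long-format CSV measurement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
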