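Package: pgcmasc
Title: Sex-Specific Expression and Transcriptomic Masculinization Analysis of Fetal Germ Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting disturbed transcriptomic sexual differentiation of
    fetal primordial germ cells after a prenatal exposure. Implements TMM
    between-sample normalization, negative-binomial GLM likelihood-ratio
    differential expression with moment-based empirically shrunk dispersions,
    sex-specific gene calling (FDR and fold-change criteria), p-value-ranked
    exposure contrasts, and the core enrichment statistic: the fraction of
    sex-specific genes among the top-k exposure-ranked genes, calibrated
    against a without-replacement permutation null with a moment-matched
    gamma fit and an exact hypergeometric oracle. A companion module ranks
    repeat-element families by whole-genome bisulfite methylation. Includes
    seeded synthetic-data generators for counts and methylation with ground
    truth, plus an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    MASS,
    fitdistrplus
Config/testthat/edition: 3
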