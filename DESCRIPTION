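Package: transpgs
Title: Simulation-Based Evaluation of Trans-Ancestry Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-ancestry genotype-phenotype cohorts with
    controllable cross-ancestry effect-size heterogeneity and evaluates the
    transferability of polygenic scores built from per-subpopulation GWAS
    summary statistics.  Four score constructions are compared: an
    ancestry-specific meta-analysis (AS), inverse-variance fixed-effects
    (FETA) and DerSimonian-Laird random-effects (RETA) trans-ancestry
    meta-analyses, and a trans-ancestry meta-regression on axes of genetic
    variation (TAMR).  Includes a Balding-Nichols synthetic allele-frequency
    panel generator, per-variant linear-model association testing,
    variance-explained evaluation under direct (individual-level) and
    indirect (summary-statistic) models, and scenario grids over
    heterogeneity and ancestry composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
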