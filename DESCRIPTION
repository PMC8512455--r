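Package: longiprot
Title: Longitudinal Proteomics Screening with Per-Protein Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screening pipeline for longitudinal biofluid proteomics in
    small-animal cohorts. Reads wide protein-intensity tables (generic or
    MaxQuant proteinGroups-style), applies two-level TMT normalization with
    pooled reference channels or log2/median centering for label-free data,
    filters proteins by per-time-point valid-value rules, fits a
    random-intercept linear mixed model per protein with categorical time
    effects, gates fits on Shapiro-Wilk normality of residuals and predicted
    random effects, tests time effects with an omnibus test, and controls the
    false discovery rate with Benjamini-Hochberg. Includes a synthetic-data
    generator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
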