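Package: immflow
Title: Immune-Ageing Pseudotime Scoring of Flow-Cytometry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a per-sample immune-ageing score (the IMM-AGE flow
    score) from gated adaptive immune cell-subset frequencies: robust
    trimmed standardization of eight informative subsets, a diffusion-map
    trajectory over samples, pseudotime measured as diffusion distance
    from a CD28-defined root, and min-max scaling to the unit interval.
    Ships the downstream cohort machinery used in trauma
    immunophenotyping studies (normality screening, two-group and
    ANOVA/Bonferroni comparisons, univariate regressions, random-forest
    ranking of sepsis-associated features with out-of-bag evaluation) and
    a synthetic cohort generator emulating a trauma/healthy-control
    longitudinal design for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
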