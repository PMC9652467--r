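Package: agewise
Title: Lifetime Trajectories of Age-Sensitive Phenotypes and
    Rate-Versus-Baseline Dissection of Anti-Aging Interventions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for multi-age-group deep-phenotyping
    studies in mice.  Classifies every phenotype in a six-age-group
    cohort as age-sensitive or not and assigns its age at first
    detectable change relative to a young-adult reference, using
    scale-appropriate omnibus tests (one-way ANOVA, Kruskal-Wallis,
    Fisher's exact) with unadjusted posthoc comparisons and a
    one-exception pattern rule.  For 2x2 young/old by control/treated
    intervention studies it fits factorial models (two-way ANOVA,
    aligned rank transform, exact tests), computes Cohen's d effect
    sizes with large-sample variances, and classifies each
    age-sensitive phenotype as countered, accentuated, unaffected or
    unevaluable, disambiguating countered phenotypes into baseline
    (age-independent shift) versus rate-or-combined (slowed
    age-dependent change) models by two independent routes:
    interaction-term inspection and two-sided z-comparison of young
    versus old effect sizes.  Cohort-level summaries include
    effect-size concordance (Pearson, two-way random-effects absolute
    agreement ICC, regression slope with test against 1), PCA with
    chained-equation imputation, standardized-coefficient forest
    tables, and exact hypergeometric gene-set overlap.  A seeded
    synthetic-cohort generator with known ground truth (onset ages,
    trajectory shapes, intervention models) supports calibration and
    recovery experiments for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
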