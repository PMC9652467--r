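---
title: "Classifying aging trajectories and dissecting rate versus baseline intervention effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying aging trajectories and dissecting rate versus baseline intervention effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewise)
```

## The scientific problem

Pro-longevity interventions — growth-hormone-pathway mutants, hypomorphic
mTOR alleles, dietary restriction regimens — are routinely credited with
"slowing aging" because treated old animals look better than untreated old
animals on age-sensitive phenotypes (ASPs).  That inference is not safe.
An intervention can normalize an old animal's phenotype in two very
different ways:

* **rate effect** — it genuinely slows the age-dependent change, so its
  effect is absent in young animals (whose phenotype has not yet changed)
  and grows with age;
* **baseline effect** — it shifts the phenotype by a constant amount at
  *every* age, including ages before any age-dependent change exists.  The
  old treated animal looks "younger", but nothing about aging has changed.

Telling these apart requires two things that many study designs omit: a
young treated group, and knowledge of the age at which each phenotype
first departs from its young-adult baseline.  `agewise` implements the
complete analysis pipeline for such designs, in three stages, plus a
synthetic-cohort generator with known ground truth so every stage can be
validated end to end.

## Stage 1 — trajectory classification

The baseline design is cross-sectional: groups of animals at 3, 5, 8, 14,
20 and 26 months (configurable; the 3-month group is the young-adult
reference).  Each phenotype is tested for *any* age effect with a
scale-appropriate omnibus test:

| scale           | omnibus            | posthoc vs reference  |
|-----------------|--------------------|-----------------------|
| continuous      | one-way ANOVA      | Fisher's LSD          |
| ordinal         | Kruskal–Wallis     | Dunn (tie-corrected)  |
| count/category  | Fisher's exact     | pairwise exact tests  |

All p-values in the pipeline are two-sided and **unadjusted**; protection
comes only from gating posthocs on a significant omnibus test
(`alpha = 0.05` throughout, configurable via `study_config()`).

A phenotype with a significant omnibus test is an ASP and receives an
**age at first detectable change** by a pattern rule over the five
posthoc comparisons against the reference: the earliest age `m` qualifies
as onset when every comparison younger than `m` is non-significant (no
exception allowed), the comparison at `m` is significant, and at most one
comparison older than `m` is non-significant (the single allowed
exception, which absorbs one unlucky posthoc in an otherwise monotone
pattern).  Patterns with no qualifying age — e.g. a midlife peak that
recovers in old age — are classed `other`.  Two readings of the published
rule were possible: the exception could or could not be allowed to fall on
the earlier (pre-onset) comparisons.  We allow it only on later
comparisons, because the defining example fixes the 3-vs-5 comparison as
non-significant before listing the exception among "all other tests"; the
rule is frozen in `assign_onset()` and tested against a literal
enumeration of all 32 significance patterns.

Direction consistency across ages is deliberately *not* part of the rule
(onset is purely significance-based); midlife-peak phenotypes are handled
by the pattern itself.

## Stage 2 — intervention classification

The intervention design is a 2x2: young/old by control/treated, with the
young group measured at ages before most ASP onsets.  Per phenotype:

* continuous: full two-way ANOVA with interaction.  Sums of squares are
  Type II by default (invariant to factor order, identical to any type on
  balanced cells), with a Type I switch.
* ordinal: aligned rank transform (ART).  For each term, responses are
  aligned (cell-mean estimates of all *other* effects subtracted), ranked
  with mid-ranks, and the factorial ANOVA is fitted on the ranks; only the
  aligned term is interpreted.  Mann–Whitney tests serve as posthocs
  within each age group.
* count/category: Fisher's exact test across the four cells.  An exact
  test cannot isolate an interaction, so `p_interaction` is `NA`,
  direction comes from category-proportion differences, and these
  phenotypes are unevaluable for the model routes below.

Three Cohen's d contrasts are computed per phenotype (pooled-SD, sign =
second group minus reference): age (old control vs young control),
treatment-in-old, and treatment-in-young, each with the large-sample
variance `var(d) = (n1+n2)/(n1 n2) + d^2/(2(n1+n2))`.  The published
analyses cite external code for the variance used in their z-tests; this
canonical form is our documented choice.  A d with a zero pooled-SD
denominator is *undefined* and propagates as "unevaluable" rather than an
error, matching how published studies report such ASPs.

Each ASP (age main effect significant *in the intervention study itself*)
is classified:

* **unaffected** — no significant intervention main effect or interaction;
* **unevaluable** — required effect sizes undefined;
* **countered** — treatment-in-old opposes the age effect's direction;
* **accentuated** — same direction.

Countered ASPs then get a rate-versus-baseline model label by two
*independent* routes, which are reported side by side and never
reconciled:

1. **interaction route**: `rate_or_combined` iff the interaction term is
   significant *and* the old-group treatment effect is larger in magnitude
   than the young-group one; otherwise `baseline`.  A significant
   interaction with a *larger young* effect is not evidence of a rate
   effect; we assign it to the baseline bucket (the conservative choice —
   the published rule's directionality filter excludes such phenotypes
   from rate-or-combined without stating their destination).
2. **effect-size route**: `rate_or_combined` iff the two-sided z-test
   comparing young and old treatment effect sizes is significant with the
   old effect larger; otherwise `baseline`.

Category fractions are reported as percentages of all ASPs, rounded
half-up to one decimal (the convention under which printed counts like
18/96 reproduce as 18.8%).

## Stage 3 — cohort-level summaries

* **Concordance** of young-vs-old treatment effect sizes per category:
  Pearson R; OLS slope of old on young with t-based 95% CI and a test of
  `slope = 1` (slope 1 = age-independent effects; significantly above 1 =
  effects larger in old); and the intraclass correlation.  The published
  analyses name only the implementing package and the "agreement"
  interpretation, so we default to the single-measurement,
  absolute-agreement, two-way random-effects variant (ICC(A,1)), which
  penalizes systematic young/old offsets; a consistency variant (ICC3) is
  selectable.
* **PCA** of all continuous phenotypes, columns z-scored (phenotypes have
  wildly different units; the published methods are silent on scaling, so
  unit-variance scaling is the default and switchable), after
  single-imputation chained equations with predictive mean matching
  (fixed 10 sweeps, donor pool 5, seeded; multiple imputation is not
  needed because the PCA is purely descriptive).  Observed values are
  never altered.
* **Forest table** of standardized coefficients: each continuous
  phenotype's 2x2 linear model on the z-scored outcome with 0/1 treatment
  coding (reference = young control) and normal-approximation 95% CIs,
  sorted by the age coefficient with the same order reused for all three
  terms.
* **Gene-set overlap**: exact hypergeometric upper tail and
  representation factor for intersecting intervention-sensitive with
  age-sensitive gene sets.

## The synthetic-cohort generator

`synthetic_spec()` fixes the study conditions; both generators are
deterministic given the seed.  Defaults: 12 animals per cell (a
representative deep-phenotyping group size), ages 3/5/8/14/20/26 months,
scale mix 60/25/15% continuous/ordinal/count, aging effects of 2 SD with
random direction, onset mix shaped like a large baseline screen (~59%
age-sensitive, most onsets in the second year of life).  Continuous noise
is Gaussian; ordinal phenotypes cut a latent Gaussian at equal-probability
thresholds into 5 levels; count phenotypes are binary lesion indicators
with a logistic age effect on a 15% base rate.  Trajectory shapes: `step`
(default), `ramp`, and the midlife-peak archetype for `other` phenotypes
(rise from 5 to a plateau at 8–14 months, back to baseline at 20–26).
Intervention models: `baseline` (shift 1.5 SD at both ages), `rate`
(fraction `rho = 1` of the age change removed, i.e. full prevention, the
cleanest test case; partial rates configurable), `combined` (1.2 SD shift
plus the rate component), `accentuate` (1.5 SD shift in the aging
direction), `null`.

What the generator does *not* emulate: between-phenotype correlation,
attrition/survivorship, body-weight covariance, and real assay-specific
group sizes.  Passing recovery tests therefore demonstrates correctness
of the statistical machinery under the stated generative models, not
robustness to those features of real data.

## Operating characteristics and the choice of experiment sizes

The package ships four experiment functions used by `analysis/05` and the
acceptance script.  Problem sizes were fixed by design, before any
results were inspected, using analytic power calculations:

* `null_calibration()`: 2000 null phenotypes per family; every family's
  rejection rate should sit in 0.05 ± 0.015 (the Monte-Carlo SE at 2000
  replicates is ~0.005).
* `onset_recovery_experiment()`: 500 step-change phenotypes, 3 SD
  effects, n = 12/group, balanced over the five onset ages.  A structural
  cap applies to late onsets: recovering a true onset of 20 (26) months
  requires 3 (4) earlier null posthocs to all stay non-significant, which
  with unadjusted tests at alpha = 0.05 and the 0.5 correlation of
  shared-reference t statistics happens with probability ~0.87 (~0.84).
  No sample size changes this — it is the price of the unadjusted-p rule
  itself — so per-category recovery above 90% is only attainable for
  onsets up to 14 months, and the headline figure is overall recovery
  (analytic expectation ~0.92).
* `intervention_recovery_experiment()`: 400 phenotypes, equal model mix,
  aging 3 SD, n = 12/cell.  The binding constraint is the effect-size
  route's z-test: distinguishing a young effect of 0 from an old effect of
  3 SD at n = 12/cell gives z ≈ 4.2 (power ~0.99); the combined model
  (1.2 vs 4.2 SD) gives z ≈ 3.5 (power ~0.94).
* `slope_discrimination_experiment()`: 200 replicate cohorts per world,
  40 phenotypes, n = 50/cell, aging magnitudes U(2.5, 3) SD with a
  consistent direction; baseline shifts of the same magnitude with random
  sign.  Two error sources shaped these numbers.  In the baseline world,
  sampling noise in the young-group d attenuates the OLS slope below 1
  (regression dilution) by roughly var(noise)/var(true effects); n =
  50/cell and sign-varying shifts keep that bias near 0.45 SE, so the CI
  still covers 1 in ~93% of replicates.  In the rate world the true young
  effects are all zero, so the fitted slope collapses to ~0; the CI
  excludes 1 reliably only if the residual spread of old effects is small
  against their mean, hence the narrow magnitude band and consistent
  aging direction.  With sign-varying aging effects the rate-world CI
  becomes uninformatively wide — a real limitation of the slope signature,
  which presupposes a dominant direction of aging among the countered
  set.

```{r operating, eval = FALSE}
null_calibration(n_rep = 2000, seed = 1)
onset_recovery_experiment(n_phenotypes = 500, seed = 1)
intervention_recovery_experiment(n_phenotypes = 400, seed = 1)
slope_discrimination_experiment(n_rep = 200, seed = 1)
```

## Numerical choices and degenerate inputs

* Mid-ranks everywhere; tie corrections in Kruskal–Wallis, Dunn and
  Mann–Whitney (normal approximation without continuity correction, so
  the two-group Dunn and Mann–Whitney p-values coincide; exact
  enumeration when n1 + n2 <= 12 and tie-free).
* Fisher's exact r x c tests use full enumeration up to N = 200 and 4x4;
  larger tables fall back to seeded Monte-Carlo (100 000 tables) with the
  seed recorded in the result.
* Zero residual variance: one-way and two-way fits report p = 0 for terms
  carrying signal and p = 1 otherwise; an all-constant response is an
  error ("degenerate") for the omnibus and a flagged F = 0, p = 1 for ART
  alignments.
* Sign ties in direction classification (|d| < 1e-12) fall back to the
  young-group effect's sign; if both are tied the phenotype is reported
  unaffected with a logged flag.
* PCA sign convention: within each component the first loading within
  1e-8 of the maximum magnitude is made positive, so equal-magnitude ties
  cannot flip with row order.  Components retained:
  min(rows - 1, columns).
* Percentages round half-up to one decimal (`round_half_up()`), not
  banker's rounding.

## Known limitations

The pipeline is strictly cross-sectional (no longitudinal or
changepoint modelling), tests are unadjusted by design (the late-onset
recovery cap above is the visible consequence), the two model routes can
and do disagree on individual phenotypes (disagreement counts are
reported, never resolved), and the slope-based discrimination assumes a
dominant aging direction within the analyzed category.  Count-scale
phenotypes never contribute to effect-size analyses.
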