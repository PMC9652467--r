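#' Type-I-error calibration of every test family under a global null
#'
#' Simulates independent null phenotypes (Gaussian noise, no effects) and
#' records the rejection rate at `alpha` of each test family used by the
#' pipeline: one-way ANOVA and Kruskal-Wallis across six age groups, and
#' each term of the parametric two-way ANOVA and of the aligned rank
#' transform on a 2x2 design.  A well-calibrated family rejects at a rate
#' close to `alpha`.
#'
#' @param n_rep null phenotypes per family (default 2000).
#' @param n_per_group animals per age group / design cell.
#' @param n_groups age groups for the one-way families.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return named numeric vector of rejection rates: `anova_oneway`,
#'   `kruskal`, `anova_twoway_age`, `anova_twoway_intervention`,
#'   `anova_twoway_interaction`, `art_age`, `art_intervention`,
#'   `art_interaction`.
#' @export
null_calibration <- function(n_rep = 2000, n_per_group = 12, n_groups = 6,
                             alpha = .aw_default_alpha, seed = 1) {
  g1 <- rep(paste0("g", seq_len(n_groups)), each = n_per_group)
  age2 <- rep(c("young", "old"), each = 2 * n_per_group)
  arm2 <- rep(c("control", "treated", "control", "treated"),
              each = n_per_group)
  withr::with_seed(seed, {
    rej <- matrix(FALSE, n_rep, 8,
                  dimnames = list(NULL, c(
                    "anova_oneway", "kruskal",
                    "anova_twoway_age", "anova_twoway_intervention",
                    "anova_twoway_interaction",
                    "art_age", "art_intervention", "art_interaction")))
    for (r in seq_len(n_rep)) {
      v1 <- rnorm(length(g1))
      rej[r, 1] <- anova_oneway(v1, g1)$p < alpha
      rej[r, 2] <- kruskal_dunn(v1, g1, "g1")$omnibus$p < alpha
      v2 <- rnorm(length(age2))
      tw <- anova_twoway(v2, age2, arm2)
      rej[r, 3:5] <- tw$p < alpha
      ar <- art_anova(v2, age2, arm2)
      rej[r, 6:8] <- ar$p < alpha
    }
    colMeans(rej)
  })
}

#' Onset-category recovery on step-change baseline cohorts
#'
#' Generates a baseline cohort in which every phenotype is a continuous
#' step-change ASP with a known onset (balanced over the five candidate
#' onset ages) and a 3-SD effect, runs the full stage-1 classification,
#' and reports recovery rates against the generative truth.
#'
#' @param n_phenotypes cohort size (default 500).
#' @param effect step size in noise-SD units (default 3).
#' @param n_per_group animals per age group (default 12).
#' @param seed integer seed.
#' @param alpha significance level.
#' @return list: `overall` (fraction of phenotypes whose assigned onset
#'   equals the generative onset), `per_category` (named vector),
#'   `confusion` (table truth x call).
#' @export
onset_recovery_experiment <- function(n_phenotypes = 500, effect = 3,
                                      n_per_group = 12, seed = 1,
                                      alpha = .aw_default_alpha) {
  spec <- synthetic_spec(
    n_phenotypes = n_phenotypes, seed = seed, n_per_cell = n_per_group,
    scale_mix = c(continuous = 1, ordinal = 0, count_category = 0),
    onset_mix = c(none = 0, m5 = 0.2, m8 = 0.2, m14 = 0.2, m20 = 0.2,
                  m26 = 0.2, other = 0),
    shape = "step", effect_age = effect)
  cohort <- generate_baseline_cohort(spec)
  study <- run_trajectory_study(cohort$table,
                                study_config(alpha = alpha, seed = seed),
                                pca = FALSE)
  truth <- cohort$truth$onset[match(study$calls$phenotype_id,
                                    cohort$truth$phenotype_id)]
  call <- study$calls$onset
  per <- vapply(unique(truth), function(tc) mean(call[truth == tc] == tc),
                numeric(1))
  list(overall = mean(call == truth),
       per_category = per[order(as.numeric(sub("^m", "", names(per))))],
       confusion = table(truth = truth, call = call))
}

map_generative_label <- function(model) {
  c(null = "unaffected", baseline = "countered_baseline",
    rate = "countered_rate_or_combined",
    combined = "countered_rate_or_combined",
    accentuate = "accentuated")[model]
}

call_category <- function(calls, route = "effectsize") {
  model <- if (route == "interaction") calls$model_interaction_route
           else calls$model_effectsize_route
  ifelse(!calls$is_asp, "not_asp",
    ifelse(calls$direction == "countered",
           ifelse(model == "rate_or_combined", "countered_rate_or_combined",
                  ifelse(model == "baseline", "countered_baseline",
                         "unevaluable")),
           calls$direction))
}

#' Intervention-model recovery on a mixed synthetic 2x2 cohort
#'
#' Generates an intervention cohort with an equal mix of the five
#' generative models (null / baseline / rate / combined / accentuate),
#' strong effects (aging 3 SD; shifts of at least 1.2 SD) and 12 animals
#' per cell, runs the stage-2 classification, and reports how often the
#' chosen route recovers each generative label (null maps to
#' "unaffected", baseline to countered-baseline, rate and combined to
#' countered-rate-or-combined, accentuate to "accentuated").
#'
#' @param n_phenotypes cohort size (default 400).
#' @param seed integer seed.
#' @param route `"effectsize"` (default) or `"interaction"`.
#' @param alpha significance level.
#' @return list: `per_label` (named recovery rates by generative model),
#'   `rate_called_baseline` (fraction of pure-rate phenotypes labelled
#'   baseline — the failure mode the design guards against), `confusion`.
#' @export
intervention_recovery_experiment <- function(n_phenotypes = 400, seed = 1,
                                             route = "effectsize",
                                             alpha = .aw_default_alpha) {
  spec <- synthetic_spec(
    n_phenotypes = n_phenotypes, seed = seed, n_per_cell = 12,
    scale_mix = c(continuous = 1, ordinal = 0, count_category = 0),
    effect_age = 3, age_direction = "random",
    model_mix = c(null = 0.2, baseline = 0.2, rate = 0.2, combined = 0.2,
                  accentuate = 0.2),
    baseline_shift = 1.5, rate_rho = 1, combined_shift = 1.2,
    accent_shift = 1.5, treat_sign = "counter")
  cohort <- generate_intervention_cohort(spec)
  study <- run_intervention_study(cohort$table,
                                  study_config(alpha = alpha, seed = seed))
  truth <- cohort$truth$model[match(study$calls$phenotype_id,
                                    cohort$truth$phenotype_id)]
  call <- call_category(study$calls, route)
  expected <- map_generative_label(truth)
  per <- vapply(unique(truth), function(m)
    mean(call[truth == m] == map_generative_label(m)), numeric(1))
  list(per_label = per,
       rate_called_baseline =
         mean(call[truth == "rate"] == "countered_baseline"),
       confusion = table(truth = truth, call = call))
}

#' Slope-based discrimination of baseline versus rate worlds
#'
#' The framework's key cohort-level signature: regressing old-group on
#' young-group treatment effect sizes should give a slope whose 95% CI
#' covers 1 when the intervention acts age-independently (baseline world:
#' identical true effects at both ages) and excludes 1 when it acts purely
#' on the age-dependent change (rate world: true young effects are zero,
#' so the fitted slope collapses towards 0 with a tight interval).
#' Replicate cohorts of each world are generated and the fraction of CIs
#' covering / excluding 1 is reported.
#'
#' Conditions (chosen by design, see the methods vignette): 40 phenotypes
#' per cohort, 50 animals per cell (so sampling noise in the young-group
#' effect sizes stays small against the spread of true effects —
#' regression dilution otherwise biases the baseline slope visibly below
#' 1), aging effects of 2.5-3 SD with a consistent direction, baseline
#' shifts of the same magnitude with random sign.
#'
#' @param n_rep replicate cohorts per world (default 200).
#' @param n_phenotypes phenotypes per cohort.
#' @param n_per_cell animals per cell.
#' @param seed integer seed.
#' @return list: `baseline_cover_1` and `rate_exclude_1` (fractions over
#'   `n_rep`), `mean_slope_baseline`, `mean_slope_rate`.
#' @export
slope_discrimination_experiment <- function(n_rep = 200, n_phenotypes = 40,
                                            n_per_cell = 50, seed = 1) {
  run_world <- function(model, treat_sign, offset) {
    cover <- logical(n_rep); slopes <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      spec <- synthetic_spec(
        n_phenotypes = n_phenotypes, seed = seed + offset + r,
        n_per_cell = n_per_cell,
        scale_mix = c(continuous = 1, ordinal = 0, count_category = 0),
        effect_age = c(2.5, 3), age_direction = "up",
        model_mix = setNames(as.numeric(names(.aw_model_names) == model),
                             names(.aw_model_names)),
        baseline_shift = c(2.5, 3), rate_rho = 1,
        treat_sign = treat_sign)
      cohort <- generate_intervention_cohort(spec)
      pairs <- treatment_effect_pairs(cohort$table)
      cs <- concordance(pairs$d_treat_young, pairs$d_treat_old)
      cover[r] <- cs$ci95[1] <= 1 && 1 <= cs$ci95[2]
      slopes[r] <- cs$slope
    }
    list(cover = mean(cover), slope = mean(slopes))
  }
  base <- run_world("baseline", "random", 0L)
  rate <- run_world("rate", "counter", 1000000L)
  list(baseline_cover_1 = base$cover,
       rate_exclude_1 = 1 - rate$cover,
       mean_slope_baseline = base$slope,
       mean_slope_rate = rate$slope)
}

.aw_model_names <- c(null = 0, baseline = 0, rate = 0, combined = 0,
                     accentuate = 0)

#' Per-phenotype treatment-effect size pairs of a 2x2 table
#'
#' Computes `(d_treat_young, d_treat_old)` for every phenotype of an
#' intervention table from the cell summaries — the raw material of the
#' concordance analyses — without fitting the factorial models.
#'
#' @param table intervention phenotype table.
#' @return data.frame: `phenotype_id`, `d_treat_young`, `d_treat_old`
#'   (`NA` when undefined).
#' @export
treatment_effect_pairs <- function(table) {
  ids <- unique(table$phenotype_id)
  rows <- lapply(ids, function(id) {
    sl <- table[table$phenotype_id == id, , drop = FALSE]
    dy <- cohens_d(cell_values(sl, "young", "control"),
                   cell_values(sl, "young", "treated"))
    do <- cohens_d(cell_values(sl, "old", "control"),
                   cell_values(sl, "old", "treated"))
    data.frame(phenotype_id = id,
               d_treat_young = if (dy$defined) dy$d else NA_real_,
               d_treat_old = if (do$defined) do$d else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
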