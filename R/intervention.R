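cell_values <- function(data, age, arm) {
  data$value[data$age_group == age & data$arm == arm]
}

#' Factorial fit and effect sizes for one phenotype of a 2x2 study
#'
#' Stage-2 per-phenotype model: continuous phenotypes get a full two-way
#' ANOVA with interaction, ordinal phenotypes the aligned rank transform
#' (with Mann-Whitney posthocs within each age group), and count/category
#' phenotypes Fisher's exact test across the four cells with margin
#' tests for age and intervention (an exact test cannot isolate an
#' interaction, so `p_interaction` is `NA` for counts).  Cohen's d effect
#' sizes are computed for the three cell contrasts that drive the
#' rate-versus-baseline classification:
#'
#' * `d_age`: old control vs young control (reference: young control);
#' * `d_treat_old`: old treated vs old control (reference: old control);
#' * `d_treat_young`: young treated vs young control.
#'
#' For count phenotypes Cohen's d is undefined; the differences in the
#' proportion of the highest category take over as direction carriers.
#'
#' @param data data.frame with columns `age_group` (`"young"`/`"old"`),
#'   `arm` (`"control"`/`"treated"`) and `value`, for one phenotype.
#' @param scale `"continuous"`, `"ordinal"` or `"count_category"`.
#' @param alpha significance level.
#' @param ss_type sums-of-squares type for the continuous route.
#' @return list of class `aw_fit`: `scale`, `p_age`, `p_intervention`,
#'   `p_interaction`, `d_age`, `d_treat_old`, `d_treat_young` (all
#'   `effect_size`), `comparison` (young-vs-old z comparison of treatment
#'   effects), `prop_effects` (for counts: named deltas in top-category
#'   proportion), `posthocs` (ordinal only).
#' @export
fit_phenotype <- function(data, scale, alpha = .aw_default_alpha,
                          ss_type = "II") {
  stopifnot(all(c("age_group", "arm", "value") %in% names(data)))
  scale <- match.arg(scale, c("continuous", "ordinal", "count_category"))
  yc <- cell_values(data, "young", "control")
  yt <- cell_values(data, "young", "treated")
  oc <- cell_values(data, "old", "control")
  ot <- cell_values(data, "old", "treated")
  if (!all(lengths(list(yc, yt, oc, ot)) >= 2L))
    stop("incomplete design: every cell needs n >= 2")

  posthocs <- NULL
  prop_effects <- NULL
  if (scale == "continuous") {
    tab <- anova_twoway(data$value, data$age_group, data$arm,
                        ss_type = ss_type)
    p_age <- tab$p[tab$term == "age"]
    p_int <- tab$p[tab$term == "intervention"]
    p_ixn <- tab$p[tab$term == "interaction"]
  } else if (scale == "ordinal") {
    tab <- art_anova(data$value, data$age_group, data$arm)
    p_age <- tab$p[tab$term == "age"]
    p_int <- tab$p[tab$term == "intervention"]
    p_ixn <- tab$p[tab$term == "interaction"]
    posthocs <- data.frame(
      age_group = c("young", "old"),
      p = c(mann_whitney(yc, yt)$p, mann_whitney(oc, ot)$p)
    )
  } else {
    cells <- factor(paste(data$age_group, data$arm, sep = "_"),
                    levels = c("young_control", "young_treated",
                               "old_control", "old_treated"))
    tab4 <- table(factor(data$value), cells)
    omnibus <- fisher_exact_table(tab4, reference = "young_control")
    p_age <- fisher_exact_table(
      table(factor(data$value), factor(data$age_group)), reference = "young"
    )$omnibus$p
    p_int <- fisher_exact_table(
      table(factor(data$value), factor(data$arm)), reference = "control"
    )$omnibus$p
    p_ixn <- NA_real_
    top <- function(v) mean(v == max(data$value))
    prop_effects <- c(age = top(oc) - top(yc),
                      treat_old = top(ot) - top(oc),
                      treat_young = top(yt) - top(yc))
  }

  if (scale == "count_category") {
    und <- function(n1, n2) new_effect_size(NA_real_, n1, n2, NA_real_,
                                            FALSE, "count-scale phenotype")
    d_age <- und(length(yc), length(oc))
    d_to <- und(length(oc), length(ot))
    d_ty <- und(length(yc), length(yt))
  } else {
    d_age <- cohens_d(yc, oc)
    d_to <- cohens_d(oc, ot)
    d_ty <- cohens_d(yc, yt)
  }
  structure(
    list(scale = scale, p_age = p_age, p_intervention = p_int,
         p_interaction = p_ixn, d_age = d_age, d_treat_old = d_to,
         d_treat_young = d_ty,
         comparison = compare_effect_sizes(d_ty, d_to, alpha),
         prop_effects = prop_effects, posthocs = posthocs,
         alpha = alpha),
    class = "aw_fit"
  )
}

sign_tol <- function(x, tol = 1e-12) {
  if (is.na(x)) return(NA_real_)
  if (abs(x) < tol) 0 else sign(x)
}

#' Direction of an intervention's influence on an age-sensitive phenotype
#'
#' Classifies one ASP of a 2x2 study by comparing the direction of the age
#' effect with the direction of the treatment effect in the old group:
#'
#' * `unaffected`: neither the intervention main effect nor the
#'   interaction is significant;
#' * `unevaluable`: the required effect sizes cannot be computed (zero
#'   pooled-SD denominator) and, for count phenotypes, the category
#'   proportions carry no direction;
#' * `countered`: the two effects point in opposite directions;
#' * `accentuated`: they point in the same direction.
#'
#' Sign ties (|d| below `1e-12`) fall back to the young-group treatment
#' effect's sign; if both are tied the phenotype is reported `unaffected`
#' with a `sign_tie` flag.
#'
#' @param fit an `aw_fit` from [fit_phenotype()].
#' @param alpha significance level.
#' @return list: `is_asp` (age main effect significant), `direction` (one
#'   of `"countered"`, `"accentuated"`, `"unaffected"`, `"unevaluable"`,
#'   or `NA` when not an ASP), `sign_tie` flag.
#' @export
classify_direction <- function(fit, alpha = .aw_default_alpha) {
  stopifnot(inherits(fit, "aw_fit"))
  is_asp <- is.finite(fit$p_age) && fit$p_age < alpha
  if (!is_asp)
    return(list(is_asp = FALSE, direction = NA_character_, sign_tie = FALSE))
  hit <- (is.finite(fit$p_intervention) && fit$p_intervention < alpha) ||
    (is.finite(fit$p_interaction) && fit$p_interaction < alpha)
  if (!hit)
    return(list(is_asp = TRUE, direction = "unaffected", sign_tie = FALSE))
  if (fit$scale == "count_category") {
    s_age <- sign_tol(fit$prop_effects["age"])
    s_old <- sign_tol(fit$prop_effects["treat_old"])
    s_young <- sign_tol(fit$prop_effects["treat_young"])
  } else {
    if (!fit$d_age$defined || !fit$d_treat_old$defined)
      return(list(is_asp = TRUE, direction = "unevaluable", sign_tie = FALSE))
    s_age <- sign_tol(fit$d_age$d)
    s_old <- sign_tol(fit$d_treat_old$d)
    s_young <- if (fit$d_treat_young$defined)
      sign_tol(fit$d_treat_young$d) else 0
  }
  tie <- FALSE
  if (s_old == 0) {              # tie-break on the young-group effect
    s_old <- s_young
    tie <- TRUE
  }
  if (s_old == 0 || s_age == 0)
    return(list(is_asp = TRUE, direction = "unaffected", sign_tie = TRUE))
  dir <- if (s_age * s_old < 0) "countered" else "accentuated"
  list(is_asp = TRUE, direction = dir, sign_tie = tie)
}

#' Rate-versus-baseline model label, interaction route
#'
#' For an ASP countered by the intervention, inspects the factorial
#' interaction term: a significant interaction together with a larger
#' treatment effect in old than in young is consistent with the rate or
#' combined rate/baseline models (the treatment acts on the age-dependent
#' change itself); a main effect without such an interaction — or an
#' interaction whose treatment effect is actually larger in young — is
#' consistent with the age-independent baseline model.
#'
#' @param fit an `aw_fit`.
#' @param direction direction string from [classify_direction()].
#' @param alpha significance level.
#' @return `"rate_or_combined"`, `"baseline"` or `"not_applicable"` (the
#'   label only applies to countered, effect-size-evaluable ASPs).
#' @export
classify_model_interaction_route <- function(fit, direction,
                                             alpha = .aw_default_alpha) {
  if (is.na(direction) || direction != "countered") return("not_applicable")
  if (!fit$d_treat_old$defined || !fit$d_treat_young$defined)
    return("not_applicable")
  ixn <- is.finite(fit$p_interaction) && fit$p_interaction < alpha
  if (ixn && abs(fit$d_treat_old$d) > abs(fit$d_treat_young$d))
    "rate_or_combined"
  else
    "baseline"
}

#' Rate-versus-baseline model label, effect-size route
#'
#' The second, independent route: the two-sided z comparison of the
#' treatment effect sizes in young versus old ([compare_effect_sizes()]).
#' A significantly larger old-group effect is consistent with the rate or
#' combined models; otherwise the baseline model (effect in old not larger
#' than in young).
#'
#' @inheritParams classify_model_interaction_route
#' @return `"rate_or_combined"`, `"baseline"` or `"not_applicable"`.
#' @export
classify_model_effectsize_route <- function(fit, direction) {
  if (is.na(direction) || direction != "countered") return("not_applicable")
  if (!fit$comparison$evaluable) return("not_applicable")
  if (fit$comparison$old_larger) "rate_or_combined" else "baseline"
}

.aw_categories <- c("unaffected", "accentuated", "unevaluable",
                    "countered_baseline", "countered_rate_or_combined")

#' Category fractions of a study's ASPs
#'
#' Splits the ASPs of one intervention study into unaffected, accentuated,
#' unevaluable, countered-baseline and countered-rate-or-combined, using
#' the model labels of the chosen route, and reports counts plus
#' percentages of all ASPs rounded half-up to one decimal.
#'
#' @param calls per-phenotype calls data.frame from
#'   [run_intervention_study()] (columns `is_asp`, `direction`,
#'   `model_interaction_route`, `model_effectsize_route`).
#' @param route `"interaction"` or `"effectsize"`.
#' @return list of class `aw_fractions`: `route`, `n_asp`, `counts` (named
#'   integer), `pct` (named numeric).
#' @export
category_fractions <- function(calls, route = c("interaction", "effectsize")) {
  route <- match.arg(route)
  asp <- calls[calls$is_asp, , drop = FALSE]
  if (nrow(asp) == 0L) stop("no age-sensitive phenotypes")
  model <- if (route == "interaction") asp$model_interaction_route
           else asp$model_effectsize_route
  cat <- ifelse(
    asp$direction == "countered",
    ifelse(model == "rate_or_combined",
           "countered_rate_or_combined",
           ifelse(model == "baseline", "countered_baseline", "unevaluable")),
    asp$direction
  )
  counts <- table(factor(cat, levels = .aw_categories))
  category_fractions_from_counts(setNames(as.integer(counts), names(counts)),
                                 route = route)
}

#' Category fractions from printed counts
#'
#' Same arithmetic as [category_fractions()] but starting from a named
#' count vector — the form in which published studies report their ASP
#' breakdowns — so printed percentages can be reproduced exactly.
#'
#' @param counts named integer vector over the categories `unaffected`,
#'   `accentuated`, `unevaluable`, `countered_baseline`,
#'   `countered_rate_or_combined`.
#' @param route label recorded in the output (no effect on arithmetic).
#' @return list of class `aw_fractions`: `route`, `n_asp`, `counts`, `pct`.
#' @export
category_fractions_from_counts <- function(counts, route = "interaction") {
  stopifnot(all(names(counts) %in% .aw_categories))
  full <- setNames(integer(length(.aw_categories)), .aw_categories)
  full[names(counts)] <- as.integer(counts)
  n_asp <- sum(full)
  if (n_asp == 0L) stop("no age-sensitive phenotypes")
  structure(
    list(route = route, n_asp = n_asp, counts = full,
         pct = round_half_up(100 * full / n_asp, 1)),
    class = "aw_fractions"
  )
}

#' @export
print.aw_fractions <- function(x, ...) {
  cat(sprintf("ASP categories (%s route; n_asp = %d):\n", x$route, x$n_asp))
  for (nm in names(x$counts))
    cat(sprintf("  %-28s %4d  (%5.1f%%)\n", nm, x$counts[nm], x$pct[nm]))
  invisible(x)
}

#' Annotate intervention calls with baseline-study onsets
#'
#' Left-joins the age-at-first-detectable-change category from a
#' trajectory (baseline) study onto the per-phenotype calls of an
#' intervention study, by `phenotype_id`.  Unmatched phenotypes keep an
#' `NA` onset; their count is reported in the `n_unmatched` attribute.
#'
#' @param calls intervention calls data.frame.
#' @param trajectory_calls trajectory calls data.frame (columns
#'   `phenotype_id`, `onset`).
#' @return `calls` with an `onset_from_baseline_study` column.
#' @export
annotate_with_baseline_onsets <- function(calls, trajectory_calls) {
  onset <- trajectory_calls$onset[match(calls$phenotype_id,
                                        trajectory_calls$phenotype_id)]
  calls$onset_from_baseline_study <- onset
  attr(calls, "n_unmatched") <- sum(is.na(onset))
  calls
}
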