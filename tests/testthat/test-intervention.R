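mk_fit <- function(p_age = 0.01, p_int = 0.5, p_ixn = 0.5,
                   d_age = 1, d_young = 0.1, d_old = -0.5,
                   n = 12, scale = "continuous") {
  es <- function(d) {
    if (is.na(d)) new_es <- structure(
      list(d = NA_real_, n1 = n, n2 = n, variance = NA_real_,
           defined = FALSE, reason = "zero pooled SD denominator"),
      class = "effect_size")
    else structure(
      list(d = d, n1 = n, n2 = n, variance = d_variance(d, n, n),
           defined = TRUE, reason = NA_character_), class = "effect_size")
  }
  dy <- es(d_young); do <- es(d_old)
  structure(list(scale = scale, p_age = p_age, p_intervention = p_int,
                 p_interaction = p_ixn, d_age = es(d_age),
                 d_treat_old = do, d_treat_young = dy,
                 comparison = compare_effect_sizes(dy, do),
                 prop_effects = NULL, posthocs = NULL, alpha = 0.05),
            class = "aw_fit")
}

test_that("direction classification follows the sign rule", {
  # opposing directions with a significant intervention effect -> countered
  f <- mk_fit(d_age = 0.9, d_old = -0.6, p_int = 0.01)
  expect_equal(classify_direction(f)$direction, "countered")
  # same direction -> accentuated
  f2 <- mk_fit(d_age = -0.5, d_old = -0.4, p_int = 0.01)
  expect_equal(classify_direction(f2)$direction, "accentuated")
  # no significant intervention or interaction term -> unaffected
  f3 <- mk_fit(d_age = 1, d_old = -2, p_int = 0.5, p_ixn = 0.5)
  expect_equal(classify_direction(f3)$direction, "unaffected")
  # undefined d in the old cells -> unevaluable
  f4 <- mk_fit(d_old = NA, p_int = 0.01)
  expect_equal(classify_direction(f4)$direction, "unevaluable")
  # not an ASP -> no direction
  f5 <- mk_fit(p_age = 0.3)
  d5 <- classify_direction(f5)
  expect_false(d5$is_asp)
  expect_true(is.na(d5$direction))
  # sign tie on d_treat_old falls back to the young-group effect
  f6 <- mk_fit(d_age = 1, d_old = 0, d_young = -0.8, p_int = 0.01)
  expect_equal(classify_direction(f6)$direction, "countered")
  expect_true(classify_direction(f6)$sign_tie)
})

test_that("interaction route separates rate-or-combined from baseline", {
  # significant interaction with larger old effect -> rate_or_combined
  f <- mk_fit(d_age = 1, d_old = -1.1, d_young = -0.2,
              p_int = 0.2, p_ixn = 0.01)
  expect_equal(classify_model_interaction_route(f, "countered"),
               "rate_or_combined")
  # main effect only -> baseline
  f2 <- mk_fit(d_age = 1, d_old = -0.8, d_young = -0.9,
               p_int = 0.001, p_ixn = 0.30)
  expect_equal(classify_model_interaction_route(f2, "countered"), "baseline")
  # significant interaction but larger young effect -> baseline bucket
  f3 <- mk_fit(d_age = 1, d_old = -0.2, d_young = -1.0,
               p_int = 0.2, p_ixn = 0.01)
  expect_equal(classify_model_interaction_route(f3, "countered"), "baseline")
  expect_equal(classify_model_interaction_route(f, "accentuated"),
               "not_applicable")
})

test_that("effect-size route keys on the z comparison", {
  # a clearly larger old effect at n = 40/cell is significant
  f <- mk_fit(d_age = 1.5, d_old = -1.8, d_young = -0.2, p_int = 0.01, n = 40)
  expect_true(f$comparison$old_larger)
  expect_equal(classify_model_effectsize_route(f, "countered"),
               "rate_or_combined")
  # comparable effects -> baseline
  f2 <- mk_fit(d_age = 1.5, d_old = -1.0, d_young = -0.9, p_int = 0.01)
  expect_equal(classify_model_effectsize_route(f2, "countered"), "baseline")
  f3 <- mk_fit(d_old = NA)
  expect_equal(classify_model_effectsize_route(f3, "countered"),
               "not_applicable")
})

test_that("category fractions reproduce printed-percentage arithmetic", {
  fr <- category_fractions_from_counts(
    c(unaffected = 35, accentuated = 18, unevaluable = 5,
      countered_baseline = 28, countered_rate_or_combined = 10))
  expect_equal(fr$n_asp, 96)
  expect_equal(unname(fr$pct["unaffected"]), 36.5)
  expect_equal(unname(fr$pct["accentuated"]), 18.8)
  fr2 <- category_fractions_from_counts(
    c(unaffected = 48, accentuated = 11, unevaluable = 1,
      countered_baseline = 28, countered_rate_or_combined = 14))
  expect_equal(unname(fr2$pct["unaffected"]), 47.1)
  # single-category corner
  fr3 <- category_fractions_from_counts(c(unevaluable = 7))
  expect_equal(unname(fr3$pct["unevaluable"]), 100.0)
  expect_error(category_fractions_from_counts(c(unaffected = 0)), "no age")
})

test_that("generative baseline and rate phenotypes produce the expected fits", {
  n <- 12
  age <- rep(c("young", "old"), each = 2 * n)
  arm <- rep(rep(c("control", "treated"), each = n), 2)
  set.seed(55)
  # baseline model: equal treatment shift at both ages
  v <- 2 * (age == "old") - 1.2 * (arm == "treated") + rnorm(4 * n, 0, 0.3)
  fit <- fit_phenotype(data.frame(age_group = age, arm = arm, value = v),
                       "continuous")
  expect_lt(fit$p_intervention, 0.001)
  expect_gt(fit$p_interaction, 0.05)
  expect_equal(abs(fit$d_treat_old$d), abs(fit$d_treat_young$d),
               tolerance = 0.5)
  # pure rate model: treatment removes the age change, nothing in young
  v2 <- 2 * (age == "old") * (1 - (arm == "treated")) + rnorm(4 * n, 0, 0.3)
  fit2 <- fit_phenotype(data.frame(age_group = age, arm = arm, value = v2),
                        "continuous")
  expect_lt(fit2$p_interaction, 0.001)
  # young effect near zero relative to the old effect (sampling noise of
  # d at n = 12 is ~0.4)
  expect_lt(abs(fit2$d_treat_young$d), 1)
  expect_lt(abs(fit2$d_treat_young$d), abs(fit2$d_treat_old$d) / 2)
  dir2 <- classify_direction(fit2)
  expect_equal(dir2$direction, "countered")
  expect_equal(classify_model_effectsize_route(fit2, dir2$direction),
               "rate_or_combined")
})

test_that("count-scale phenotypes classify by proportions, no model routes", {
  n <- 15
  age <- rep(c("young", "old"), each = 2 * n)
  arm <- rep(rep(c("control", "treated"), each = n), 2)
  # lesions appear with age, treatment prevents them in old animals
  v <- c(rep(0, n), rep(0, n), rep(1, n), rep(c(0, 1), c(12, 3)))
  fit <- fit_phenotype(data.frame(age_group = age, arm = arm, value = v),
                       "count_category")
  expect_true(is.na(fit$p_interaction))
  expect_false(fit$d_age$defined)
  dir <- classify_direction(fit)
  expect_equal(dir$direction, "countered")
  expect_equal(classify_model_interaction_route(fit, dir$direction),
               "not_applicable")
})

test_that("baseline-onset annotation is a left join and idempotent", {
  calls <- data.frame(phenotype_id = c("a", "b", "c"), is_asp = TRUE)
  traj <- data.frame(phenotype_id = c("a", "c"), onset = c("m8", "m20"))
  an <- annotate_with_baseline_onsets(calls, traj)
  expect_equal(an$onset_from_baseline_study, c("m8", NA, "m20"))
  expect_equal(attr(an, "n_unmatched"), 1L)
  an2 <- annotate_with_baseline_onsets(an, traj)
  expect_equal(an2$onset_from_baseline_study, an$onset_from_baseline_study)
  # empty trajectory input -> all onsets absent
  an3 <- annotate_with_baseline_onsets(
    calls, data.frame(phenotype_id = character(0), onset = character(0)))
  expect_true(all(is.na(an3$onset_from_baseline_study)))
})
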