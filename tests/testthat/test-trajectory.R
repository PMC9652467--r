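pp <- function(...) {
  # posthoc p vector over the five later ages; sig = 0.01, ns = 0.4
  v <- c(...)
  setNames(ifelse(v == 1, 0.01, 0.4), c("5", "8", "14", "20", "26"))
}

test_that("onset rule reproduces the canonical patterns", {
  # first change at 8 months: 5 ns, all later significant
  r <- assign_onset(pp(0, 1, 1, 1, 1), TRUE)
  expect_equal(r$onset, "m8")
  expect_false(r$exception_used)
  # one later non-significant comparison is excused
  r2 <- assign_onset(pp(0, 1, 0, 1, 1), TRUE)
  expect_equal(r2$onset, "m8")
  expect_true(r2$exception_used)
  # early blip followed by recovery does not qualify anywhere
  r3 <- assign_onset(pp(1, 0, 0, 0, 0), TRUE)
  expect_equal(r3$onset, "other")
  # non-significant omnibus always gives none
  expect_equal(assign_onset(pp(0, 1, 1, 1, 1), FALSE)$onset, "none")
  # earlier comparisons get no exception: significant 5 blocks m8
  expect_equal(assign_onset(pp(1, 1, 1, 1, 1), TRUE)$onset, "m5")
  expect_equal(assign_onset(pp(1, 1, 0, 0, 1), TRUE)$onset, "other")
  # last age can qualify (no later comparisons to excuse)
  r26 <- assign_onset(pp(0, 0, 0, 0, 1), TRUE)
  expect_equal(r26$onset, "m26")
  expect_false(r26$exception_used)
  expect_error(assign_onset(c("5" = 0.1, "8" = NA), TRUE), "incomplete")
})

test_that("onset rule agrees with the literal-rule oracle on all 32 patterns", {
  for (code in 0:31) {
    sig <- as.logical(bitwAnd(code, 2^(0:4)))
    p <- setNames(ifelse(sig, 0.001, 0.9), c("5", "8", "14", "20", "26"))
    for (om in c(TRUE, FALSE)) {
      expect_equal(assign_onset(p, om)$onset, oracle_onset(sig, om),
                   info = paste("pattern", code, "omnibus", om))
    }
  }
})

test_that("scale dispatch picks the right omnibus family", {
  spec <- synthetic_spec(n_phenotypes = 3, seed = 77, n_per_cell = 10,
                         scale_mix = c(continuous = 1/3, ordinal = 1/3,
                                       count_category = 1/3),
                         onset_mix = c(none = 0, m5 = 0, m8 = 1, m14 = 0,
                                       m20 = 0, m26 = 0, other = 0),
                         effect_age = 3)
  cohort <- generate_baseline_cohort(spec)
  for (id in unique(cohort$table$phenotype_id)) {
    sl <- cohort$table[cohort$table$phenotype_id == id, ]
    cl <- classify_age_sensitivity(sl, sl$scale[1])
    expected <- switch(sl$scale[1], continuous = "anova1",
                       ordinal = "kruskal", count_category = "fisher_exact")
    expect_equal(cl$omnibus$method, expected)
    expect_equal(nrow(cl$posthocs), 5)
  }
  # reference group must be present
  sl <- cohort$table[cohort$table$phenotype_id == "p0001" &
                       cohort$table$age_months > 3, ]
  expect_error(classify_age_sensitivity(sl, sl$scale[1], reference_age = 3),
               "missing reference")
})

test_that("null continuous phenotypes are rarely called age-sensitive", {
  set.seed(19)
  calls <- replicate(200, {
    v <- rnorm(36)
    g <- rep(c(3, 5, 8, 14, 20, 26), each = 6)
    classify_age_sensitivity(data.frame(age_months = g, value = v),
                             "continuous")$age_sensitive
  })
  expect_lt(mean(calls), 0.11)   # ~ alpha, generous binomial margin
  # constant ordinal phenotype: Kruskal-Wallis p = 1
  cl <- classify_age_sensitivity(
    data.frame(age_months = rep(c(3, 5, 8, 14, 20, 26), each = 4),
               value = rep(2, 24)), "ordinal")
  expect_equal(cl$omnibus$p, 1)
  expect_false(cl$age_sensitive)
})

test_that("trajectory summary arithmetic and rounding", {
  calls <- data.frame(
    phenotype_id = sprintf("p%02d", 1:10),
    age_sensitive = rep(c(TRUE, FALSE), c(6, 4)),
    onset = c(rep("m14", 3), "m5", "m20", "other", rep("none", 4)))
  s <- summarize_trajectories(calls)
  expect_equal(s$n_asp, 6)
  expect_equal(s$pct_asp, 60.0)
  expect_equal(s$onsets$pct_of_asp[s$onsets$onset == "m14"], 50.0)
  # all none
  s0 <- summarize_trajectories(data.frame(phenotype_id = "a",
                                          age_sensitive = FALSE,
                                          onset = "none"))
  expect_equal(s0$n_asp, 0)
  expect_equal(nrow(s0$onsets), 0)
})

test_that("onset recovery: early categories are recovered reliably and", {
  # late-onset misses land where the rule predicts (earlier false
  # positives pull calls to earlier onsets or to other, never to none)
  rec <- onset_recovery_experiment(n_phenotypes = 150, seed = 7)
  expect_gt(rec$per_category[["m5"]], 0.9)
  expect_gt(rec$per_category[["m8"]], 0.9)
  conf <- rec$confusion
  expect_equal(sum(conf[, colnames(conf) == "none"]), 0)
})
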