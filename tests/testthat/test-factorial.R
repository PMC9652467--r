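mk2x2 <- function(n, f, noise = 0, seed = NULL) {
  # f(age01, arm01) gives the cell mean
  age <- rep(c("young", "old"), each = 2 * n)
  arm <- rep(rep(c("control", "treated"), each = n), 2)
  mu <- f(as.numeric(age == "old"), as.numeric(arm == "treated"))
  if (!is.null(seed)) set.seed(seed)
  list(values = mu + rnorm(length(mu), 0, noise), age = age, arm = arm)
}

test_that("two-way ANOVA separates generative age and intervention signals", {
  d <- mk2x2(10, function(o, t) 3 * o, noise = 0.1, seed = 2)
  tab <- anova_twoway(d$values, d$age, d$arm)
  expect_lt(tab$p[tab$term == "age"], 1e-6)
  expect_gt(tab$p[tab$term == "intervention"], 0.05)
  expect_gt(tab$p[tab$term == "interaction"], 0.05)
})

test_that("balanced two-way F statistics match a cell-mean SS oracle", {
  d <- mk2x2(3, function(o, t) 1 + o - 0.5 * t + 2 * o * t,
             noise = 1, seed = 4)
  tab <- anova_twoway(d$values, d$age, d$arm)
  # brute-force decomposition from cell means (balanced, n = 3)
  cm <- tapply(d$values, list(d$age, d$arm), mean)
  n <- 3; grand <- mean(cm)
  ss_a <- 2 * n * sum((rowMeans(cm) - grand)^2)
  ss_b <- 2 * n * sum((colMeans(cm) - grand)^2)
  ss_ab <- n * sum((sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + grand)^2)
  ss_e <- sum((d$values - cm[cbind(d$age, d$arm)])^2)
  mse <- ss_e / (12 - 4)
  expect_equal(tab$statistic, c(ss_a, ss_b, ss_ab) / mse, tolerance = 1e-10)
  # additive cell means with zero noise -> zero interaction SS
  d0 <- mk2x2(3, function(o, t) 2 + o + 4 * t)
  tab0 <- anova_twoway(d0$values, d0$age, d0$arm)
  expect_equal(tab0$p[tab0$term == "interaction"], 1)
})

test_that("Type II and Type I agree on balanced designs", {
  d <- mk2x2(6, function(o, t) o + t, noise = 1, seed = 8)
  t2 <- anova_twoway(d$values, d$age, d$arm, ss_type = "II")
  t1 <- anova_twoway(d$values, d$age, d$arm, ss_type = "I")
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-10)
})

test_that("incomplete 2x2 designs are rejected", {
  expect_error(
    anova_twoway(rnorm(9), rep(c("young", "old", "old"), 3),
                 rep("control", 9)),
    "incomplete design")
})

test_that("ART alignment strips every effect except the aligned one", {
  d <- mk2x2(4, function(o, t) 1 + 2 * o + 3 * t + 1.5 * o * t)
  for (tm in c("age", "intervention", "interaction")) {
    al <- art_align(d$values, d$age, d$arm, tm)
    expect_equal(sum(al), 0, tolerance = 1e-10)      # aligned sum ~ 0
    tab <- anova_twoway(al, d$age, d$arm)
    others <- setdiff(tab$term, tm)
    expect_true(all(tab$statistic[tab$term %in% others] < 1e-8))
  }
})

test_that("ART results equal an independent step-by-step oracle", {
  set.seed(13)
  for (i in 1:8) {
    d <- mk2x2(5, function(o, t) o * runif(1, -1, 1) + t * runif(1, -1, 1),
               noise = 1)
    res <- art_anova(d$values, d$age, d$arm)
    for (tm in c("age", "intervention", "interaction")) {
      orc <- oracle_art(d$values, d$age, d$arm, tm)
      row <- res[res$term == tm, ]
      expect_equal(row$statistic, unname(orc$F), tolerance = 1e-9)
      expect_equal(row$p, unname(orc$p), tolerance = 1e-9)
    }
  }
})

test_that("degenerate ART alignment is flagged with F = 0, p = 1", {
  d <- mk2x2(3, function(o, t) 0 * o)
  res <- art_anova(d$values, d$age, d$arm)
  expect_true(all(res$degenerate))
  expect_equal(res$p, rep(1, 3))
})

test_that("standardized coefficients match the normal-equations oracle", {
  d <- mk2x2(4, function(o, t) 2 * o - t, noise = 1, seed = 17)
  co <- standardized_lm(d$values, d$age, d$arm)
  orc <- oracle_std_coefs(d$values, d$age, d$arm)
  expect_equal(co$estimate, unname(orc), tolerance = 1e-10)
  # scale invariance: doubling raw values leaves standardized coefs alone
  co2 <- standardized_lm(2 * d$values, d$age, d$arm)
  expect_equal(co2$estimate, co$estimate, tolerance = 1e-12)
  # CIs symmetric about the estimate
  expect_equal(co$ci_hi - co$estimate, co$estimate - co$ci_lo,
               tolerance = 1e-12)
  # pure 1-SD additive age effect on an already standardized outcome
  d3 <- mk2x2(50, function(o, t) o, noise = 1e-8, seed = 23)
  co3 <- standardized_lm(d3$values, d3$age, d3$arm)
  # outcome z-scoring rescales the raw 1-unit effect by the outcome SD
  expect_equal(co3$estimate[co3$term == "age"], 1 / sd(d3$values),
               tolerance = 1e-4)
  expect_equal(co3$estimate[co3$term == "interaction"], 0, tolerance = 1e-4)
  expect_error(standardized_lm(rep(1, 16), d$age, d$arm), "constant")
})
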