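test_that("one-way ANOVA reproduces hand sums of squares and edge conventions", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_oneway(v, g)
  expect_equal(res$statistic, 3)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, 0.125)          # closed form (1 + 2F/df2)^(-df2/2)
  # identical means, nonzero spread -> F = 0, p = 1
  res0 <- anova_oneway(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # zero within-group variance with unequal means -> p = 0 convention
  resz <- anova_oneway(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(resz$p, 0)
  expect_error(anova_oneway(rep(2, 6), rep(c("a", "b"), each = 3)),
               "degenerate")
})

test_that("one-way ANOVA and LSD match brute-force oracles on random data", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    ns <- sample(3:7, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), ns)
    v <- rnorm(length(g)) + rep(runif(k, -1, 1), ns)
    res <- anova_oneway(v, g)
    orc <- oracle_oneway_F(v, g)
    expect_equal(res$statistic, orc$F)
    expect_equal(res$p, orc$p)
    ph <- fisher_lsd(v, g, "g1")
    for (j in 2:k)
      expect_equal(ph$p[ph$group == paste0("g", j)],
                   oracle_lsd_p(v, g, paste0("g", j), "g1"))
  }
})

test_that("LSD example and two-group identities hold", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  ph <- fisher_lsd(v, g, "a")
  expect_equal(ph$statistic[ph$group == "c"], 2 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ph$df[1], 6)
  expect_equal(ph$p[ph$group == "c"], 2 * pt(-2 / sqrt(2 / 3), 6))
  # group identical to reference -> p = 1, sign 0
  v2 <- c(1, 2, 3, 1, 2, 3, 9, 9, 8)
  ph2 <- fisher_lsd(v2, g, "a")
  expect_equal(ph2$p[ph2$group == "b"], 1)
  expect_equal(ph2$sign[ph2$group == "b"], 0)
  # two groups: LSD p equals pooled two-sample t-test p; F = t^2
  set.seed(3)
  x <- rnorm(8); y <- rnorm(9) + 0.8
  v3 <- c(x, y); g3 <- rep(c("a", "b"), c(8, 9))
  tt <- t.test(y, x, var.equal = TRUE)
  ph3 <- fisher_lsd(v3, g3, "a")
  expect_equal(ph3$p, tt$p.value)
  expect_equal(anova_oneway(v3, g3)$statistic, unname(tt$statistic)^2)
})

test_that("Kruskal-Wallis/Dunn match rank-formula oracles, with ties", {
  set.seed(21)
  for (i in 1:15) {
    k <- sample(3:4, 1)
    g <- rep(paste0("g", seq_len(k)), each = sample(4:6, 1))
    v <- sample(1:5, length(g), replace = TRUE)    # heavy ties
    kd <- kruskal_dunn(v, g, "g1")
    expect_equal(kd$omnibus$statistic, oracle_kruskal_H(v, g),
                 tolerance = 1e-10)
    for (j in 2:k) {
      z <- oracle_dunn_z(v, g, paste0("g", j), "g1")
      row <- kd$posthocs[kd$posthocs$group == paste0("g", j), ]
      expect_equal(row$statistic, z, tolerance = 1e-10)
      expect_equal(row$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
    }
  }
  # label permutation leaves H invariant
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  perm <- c(a = "c", b = "a", c = "b")
  expect_equal(kruskal_dunn(v, g, "a")$omnibus$statistic,
               kruskal_dunn(v, perm[g], "c")$omnibus$statistic)
  # all tied -> H = 0, p = 1
  flat <- kruskal_dunn(rep(2, 9), g, "a")
  expect_equal(flat$omnibus$p, 1)
  expect_equal(flat$posthocs$p, c(1, 1))
})

test_that("two-group Dunn equals the tie-corrected normal Mann-Whitney", {
  set.seed(5)
  x <- sample(1:6, 10, replace = TRUE)
  y <- sample(2:8, 12, replace = TRUE)
  kd <- kruskal_dunn(c(x, y), rep(c("a", "b"), c(10, 12)), "a")
  mw <- mann_whitney(x, y)
  expect_equal(kd$posthocs$p, mw$p, tolerance = 1e-10)
})

test_that("Mann-Whitney agrees with exact enumeration and is symmetric", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(sample(3:5, 1)); y <- rnorm(sample(3:5, 1))
    expect_equal(mann_whitney(x, y)$p, oracle_mwu_p(x, y), tolerance = 1e-10)
    expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  }
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Fisher's exact test matches enumeration over margin-fixed tables", {
  tab <- matrix(c(3, 0, 0, 3), 2)
  expect_equal(fisher_exact_table(tab)$omnibus$p, 0.1)
  expect_equal(fisher_exact_table(t(tab))$omnibus$p, 0.1)   # transpose
  same <- matrix(c(2, 3, 2, 3), 2)
  expect_equal(fisher_exact_table(same)$omnibus$p, 1)       # identical columns
  set.seed(31)
  for (i in 1:12) {
    repeat {
      tb <- matrix(rpois(sample(c(4, 6), 1), 1.3), nrow = 2)
      if (sum(tb) <= 12 && all(rowSums(tb) > 0) && all(colSums(tb) > 0)) break
    }
    expect_equal(fisher_exact_table(tb)$omnibus$p, oracle_fisher_p(tb),
                 tolerance = 1e-9)
  }
  # zero-margin column is dropped with a warning
  zm <- matrix(c(3, 0, 0, 0, 2, 4), 2)
  expect_warning(res <- fisher_exact_table(zm, reference = 1),
                 "zero-margin")
})

test_that("hypergeometric overlap matches enumeration and is monotone", {
  h <- hypergeom_overlap(10, 5, 4, 4)
  expect_equal(h$expected, 2)
  expect_equal(h$representation_factor, 2)
  expect_equal(h$p, 5 / 210)
  for (N in c(8, 10, 12)) for (k in 0:3) {
    A <- 5; B <- 4
    if (k <= min(A, B))
      expect_equal(hypergeom_overlap(N, A, B, k)$p,
                   oracle_hypergeom_p(N, A, B, k), tolerance = 1e-12)
  }
  ps <- vapply(0:4, function(k) hypergeom_overlap(10, 5, 4, k)$p, 0)
  rf <- vapply(0:4, function(k) hypergeom_overlap(10, 5, 4, k)$representation_factor, 0)
  expect_true(all(diff(ps) < 0))     # p decreasing in overlap
  expect_true(all(diff(rf) > 0))     # RF increasing in overlap
  expect_error(hypergeom_overlap(10, 0, 4, 0), "undefined")
})
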