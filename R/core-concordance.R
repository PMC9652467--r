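#' Concordance of young-group versus old-group effect sizes
#'
#' Quantifies how similar intervention effects are across age groups for a
#' set of phenotypes, given paired effect sizes `x` (young group) and `y`
#' (old group).  Three complementary statistics are reported:
#'
#' * Pearson correlation with its t-test p-value;
#' * ordinary least-squares slope of `y` on `x` with SE, a t-based 95%
#'   confidence interval (df = n - 2) and a two-sided test of the null
#'   `slope = 1` (slope 1 = identical effects at both ages; slopes
#'   significantly above 1 = effects larger in old animals);
#' * intraclass correlation, by default the single-measurement,
#'   absolute-agreement, two-way random-effects variant (often written
#'   ICC(A,1) or ICC2), which penalizes systematic young/old offsets that a
#'   plain correlation ignores, with its F-test p-value.
#'
#' @param x,y numeric vectors of paired effect sizes (young, old).
#' @param icc_type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency, two-way mixed).
#' @param conf confidence level for the slope interval.
#' @return list of class `aw_concordance`: `n_pairs`, `pearson_r`, `p_r`,
#'   `icc`, `icc_type`, `p_icc`, `slope`, `se_slope`, `ci95` (length-2),
#'   `intercept`, `p_slope_vs_1`.
#' @details Degenerate cases: constant `x` is an error (the slope is
#'   undefined); zero residual variance gives `p_slope_vs_1 = 1` when the
#'   slope is exactly 1 and 0 otherwise.
#' @export
concordance <- function(x, y, icc_type = c("ICC2", "ICC3"), conf = 0.95) {
  icc_type <- match.arg(icc_type)
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient pairs: need at least 3")
  if (sd(x) == 0) stop("constant x: slope undefined")

  # Pearson
  if (sd(y) == 0) {
    pearson_r <- NA_real_; p_r <- NA_real_
  } else {
    ct <- cor.test(x, y)
    pearson_r <- unname(ct$estimate); p_r <- ct$p.value
  }

  # OLS of y on x, test against slope 1
  mod <- lm(y ~ x)
  slope <- unname(coef(mod)[2])
  sse <- sum(resid(mod)^2)
  if (sse < 1e-12 * max(1, sum(y^2))) {
    se_slope <- 0
    p_slope <- if (abs(slope - 1) < 1e-12) 1 else 0
    ci <- c(slope, slope)
  } else {
    se_slope <- summary(mod)$coefficients[2, 2]
    tq <- qt(1 - (1 - conf) / 2, n - 2)
    ci <- c(slope - tq * se_slope, slope + tq * se_slope)
    p_slope <- 2 * pt(-abs((slope - 1) / se_slope), n - 2)
  }

  # ICC from the two-way mean squares (rows = phenotypes, k = 2 raters)
  k <- 2
  m <- cbind(x, y)
  rowm <- rowMeans(m); colm <- colMeans(m); grand <- mean(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  icc <- if (icc_type == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  f_icc <- if (mse == 0) Inf else msr / mse
  p_icc <- pf(f_icc, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(
    list(n_pairs = n, pearson_r = pearson_r, p_r = p_r,
         icc = icc, icc_type = icc_type, p_icc = p_icc,
         slope = slope, se_slope = se_slope, ci95 = ci,
         intercept = unname(coef(mod)[1]), p_slope_vs_1 = p_slope),
    class = "aw_concordance"
  )
}

#' @export
print.aw_concordance <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d pairs: R = %.3f (p = %.3g), %s = %.3f (p = %.3g)\n",
    x$n_pairs, x$pearson_r, x$p_r, x$icc_type, x$icc, x$p_icc))
  cat(sprintf("  slope = %.3f +/- %.3f (95%% CI %.3f, %.3f; p vs 1 = %.4g)\n",
              x$slope, x$se_slope, x$ci95[1], x$ci95[2], x$p_slope_vs_1))
  invisible(x)
}

#' Exact hypergeometric overlap of two gene sets
#'
#' Upper-tail exact test of whether two subsets of a finite universe
#' overlap more than expected under independence, with the representation
#' factor `RF = observed / expected`, `expected = setA_n * setB_n /
#' universe_n`.  Used to intersect intervention-sensitive and age-sensitive
#' gene sets.
#'
#' @param universe_n size of the universe.
#' @param seta_n,setb_n sizes of the two sets.
#' @param overlap_n observed overlap.
#' @return list: `universe_n`, `seta_n`, `setb_n`, `overlap_n`, `expected`,
#'   `representation_factor`, `p` (P(X >= overlap)).
#' @export
hypergeom_overlap <- function(universe_n, seta_n, setb_n, overlap_n) {
  stopifnot(seta_n <= universe_n, setb_n <= universe_n,
            overlap_n <= min(seta_n, setb_n), overlap_n >= 0)
  expected <- seta_n * setb_n / universe_n
  if (expected == 0) stop("expected overlap is zero; representation factor undefined")
  p <- stats::phyper(overlap_n - 1, seta_n, universe_n - seta_n, setb_n,
                     lower.tail = FALSE)
  list(universe_n = universe_n, seta_n = seta_n, setb_n = setb_n,
       overlap_n = overlap_n, expected = expected,
       representation_factor = overlap_n / expected, p = p)
}
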