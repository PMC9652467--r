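check_twoway <- function(values, age, arm) {
  age <- as.character(age); arm <- as.character(arm)
  if (length(values) != length(age) || length(values) != length(arm))
    stop("values, age and arm must have equal length")
  if (length(unique(age)) != 2L || length(unique(arm)) != 2L)
    stop("incomplete design: need exactly two age groups and two arms")
  cells <- table(age, arm)
  if (any(cells < 2L))
    stop("incomplete design: every cell needs n >= 2")
  list(age = age, arm = arm)
}

# order factor levels so that the reference cell (young, control) comes
# first when the conventional labels are used
aw_factor <- function(x, preferred_first = c("young", "control")) {
  lv <- unique(x)
  first <- intersect(preferred_first, lv)
  if (length(first) == 1L) lv <- c(first, setdiff(lv, first))
  factor(x, levels = lv)
}

#' Two-way between-subjects ANOVA with interaction
#'
#' Full two-factor linear model `value ~ age * intervention` for 2x2
#' young/old by control/treated designs.  Type II sums of squares by
#' default (order-invariant; identical to any type when cells are
#' balanced), computed via [car::Anova()]; sequential Type I available via
#' `ss_type = "I"`.
#'
#' @param values numeric vector.
#' @param age age-group labels (two levels, e.g. "young"/"old").
#' @param arm study-arm labels (two levels, e.g. "control"/"treated").
#' @param ss_type `"II"` (default) or `"I"`.
#' @return data.frame with rows `age`, `intervention`, `interaction`:
#'   columns `term`, `statistic` (F), `df1`, `df2`, `p`.
#' @export
anova_twoway <- function(values, age, arm, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  ck <- check_twoway(values, age, arm)
  fa <- aw_factor(ck$age); fb <- aw_factor(ck$arm)
  mod <- lm(values ~ fa * fb)
  rows <- c("fa", "fb", "fa:fb")
  rss <- sum(resid(mod)^2)
  if (rss < 1e-10 * max(1, sum((values - mean(values))^2))) {
    # zero residual variance: terms carrying signal are maximally
    # significant by convention (sequential SS suffice to detect signal)
    tab <- suppressWarnings(anova(mod))
    ssq <- tab[rows, "Sum Sq"]
    df1 <- tab[rows, "Df"]; df2 <- tab["Residuals", "Df"]
    Fv <- ifelse(ssq > 1e-10, Inf, 0)
    pv <- ifelse(ssq > 1e-10, 0, 1)
  } else if (ss_type == "II") {
    tab <- car::Anova(mod, type = 2)
    Fv <- tab[rows, "F value"]; df1 <- tab[rows, "Df"]
    pv <- tab[rows, "Pr(>F)"]; df2 <- tab["Residuals", "Df"]
  } else {
    tab <- anova(mod)
    Fv <- tab[rows, "F value"]; df1 <- tab[rows, "Df"]
    pv <- tab[rows, "Pr(>F)"]; df2 <- tab["Residuals", "Df"]
  }
  data.frame(term = c("age", "intervention", "interaction"),
             statistic = unname(Fv), df1 = unname(df1),
             df2 = rep(unname(df2), 3), p = unname(pv),
             stringsAsFactors = FALSE)
}

#' Aligned responses for one effect of a 2x2 factorial design
#'
#' Standard aligned-rank-transform decomposition: each observation is
#' stripped of every estimated effect except the one of interest, i.e.
#' `y - cellmean + effect_T`, where the effects are estimated from the
#' (unweighted) cell means.  ANOVA on the aligned (pre-rank) responses
#' yields F = 0 for every effect other than `term` on balanced data; that
#' property is the defining sanity check of the procedure.
#'
#' @param values numeric vector.
#' @param age,arm factor labels as in [anova_twoway()].
#' @param term `"age"`, `"intervention"` or `"interaction"`.
#' @return numeric vector of aligned responses.
#' @export
art_align <- function(values, age, arm,
                      term = c("age", "intervention", "interaction")) {
  term <- match.arg(term)
  ck <- check_twoway(values, age, arm)
  a <- ck$age; b <- ck$arm
  cell <- tapply(values, list(a, b), mean)
  grand <- mean(cell)
  rowm <- rowMeans(cell); colm <- colMeans(cell)
  eff <- switch(term,
    age          = rowm[a] - grand,
    intervention = colm[b] - grand,
    interaction  = cell[cbind(a, b)] - rowm[a] - colm[b] + grand
  )
  unname(values - cell[cbind(a, b)] + eff)
}

#' Aligned Rank Transform factorial ANOVA
#'
#' Nonparametric analysis of a 2x2 design: for each term, responses are
#' aligned for that term ([art_align()]), converted to mid-ranks, and the
#' full two-factor ANOVA is fitted on the ranks; only the aligned term's F
#' and p are interpreted and reported.
#'
#' @inheritParams anova_twoway
#' @return data.frame with rows `age`, `intervention`, `interaction`:
#'   `term`, `statistic`, `df1`, `df2`, `p`, `degenerate` (TRUE when the
#'   alignment left all ranks tied, in which case F = 0 and p = 1 are
#'   reported).
#' @export
art_anova <- function(values, age, arm) {
  check_twoway(values, age, arm)
  terms <- c("age", "intervention", "interaction")
  rows <- lapply(terms, function(tm) {
    al <- art_align(values, age, arm, tm)
    r <- rank(al)
    if (var(r) == 0) {
      return(data.frame(term = tm, statistic = 0, df1 = 1,
                        df2 = length(values) - 4, p = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tab <- anova_twoway(r, age, arm)
    out <- tab[tab$term == tm, , drop = FALSE]
    out$degenerate <- FALSE
    out
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Standardized coefficients of the full 2x2 linear model
#'
#' Fits `z(value) ~ old + treated + old:treated` where the outcome is
#' z-scored and the predictors are 0/1 indicators (treatment coding,
#' reference = young control), and reports each coefficient in outcome-SD
#' units with a normal-approximation 95% confidence interval.  These are
#' the rows of the forest-plot table comparing age, intervention and
#' interaction effects across phenotypes.
#'
#' @inheritParams anova_twoway
#' @param conf level of the (normal) confidence interval.
#' @return data.frame with rows `age`, `intervention`, `interaction`:
#'   `term`, `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
standardized_lm <- function(values, age, arm, conf = 0.95) {
  ck <- check_twoway(values, age, arm)
  if (sd(values) == 0) stop("constant phenotype")
  z <- (values - mean(values)) / sd(values)
  old <- as.numeric(aw_factor(ck$age)) - 1      # 0 = young, 1 = old
  trt <- as.numeric(aw_factor(ck$arm)) - 1      # 0 = control, 1 = treated
  mod <- lm(z ~ old * trt)
  sm <- summary(mod)$coefficients
  q <- qnorm(1 - (1 - conf) / 2)
  est <- sm[c("old", "trt", "old:trt"), "Estimate"]
  se  <- sm[c("old", "trt", "old:trt"), "Std. Error"]
  data.frame(term = c("age", "intervention", "interaction"),
             estimate = unname(est), se = unname(se),
             ci_lo = unname(est - q * se), ci_hi = unname(est + q * se),
             stringsAsFactors = FALSE)
}
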