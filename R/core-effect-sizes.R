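#' Per-group descriptive statistics
#'
#' Summarizes a set of measurements by group label, using the sample
#' (n - 1 denominator) standard deviation.  These are the per-cell means and
#' SDs underlying all downstream effect-size computations.
#'
#' @param values numeric vector of measurements.
#' @param groups vector of group labels, same length as `values`.
#' @return A data.frame with one row per group (in order of first
#'   appearance): `group`, `n`, `mean`, `sd`.  `sd` is `NA` for singleton
#'   groups, where it is undefined.
#' @export
summarize_groups <- function(values, groups) {
  if (length(values) == 0L) stop("no data")
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length")
  groups <- as.character(groups)
  sp <- split(values, factor(groups, levels = unique(groups)))
  data.frame(
    group = names(sp),
    n     = vapply(sp, length, integer(1)),
    mean  = vapply(sp, mean, numeric(1)),
    sd    = vapply(sp, function(v) if (length(v) >= 2L) sd(v) else NA_real_,
                   numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

new_effect_size <- function(d, n1, n2, variance, defined, reason = NA_character_) {
  structure(
    list(d = d, n1 = n1, n2 = n2, variance = variance,
         defined = defined, reason = reason),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  if (x$defined)
    cat(sprintf("Cohen's d = %.4g (n = %d, %d; var = %.4g)\n",
                x$d, x$n1, x$n2, x$variance))
  else
    cat(sprintf("Cohen's d undefined (%s)\n", x$reason))
  invisible(x)
}

#' Cohen's d standardized mean difference
#'
#' Pooled-SD standardized mean difference between two groups.  The sign
#' convention is `(mean(other) - mean(ref)) / pooled SD`, so a positive value
#' means `other` lies above the reference group.  The effect size is
#' undefined (`defined = FALSE`) when either group has fewer than two
#' observations or when the pooled SD is zero (e.g. a phenotype constant in
#' both groups); undefined effect sizes propagate as "unevaluable" through
#' the intervention classifier rather than erroring.
#'
#' @param ref numeric vector, reference group.
#' @param other numeric vector, comparison group.
#' @return An `effect_size` object: `d`, `n1`, `n2`, `variance` (large-sample
#'   variance of d, see [d_variance()]), `defined`, `reason`.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # d = 2
cohens_d <- function(ref, other) {
  n1 <- length(ref); n2 <- length(other)
  if (n1 < 2L || n2 < 2L)
    return(new_effect_size(NA_real_, n1, n2, NA_real_, FALSE,
                           "fewer than 2 observations in a group"))
  s1 <- sd(ref); s2 <- sd(other)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0)
    return(new_effect_size(NA_real_, n1, n2, NA_real_, FALSE,
                           "zero pooled SD denominator"))
  d <- (mean(other) - mean(ref)) / sp
  new_effect_size(d, n1, n2, d_variance(d, n1, n2), TRUE)
}

#' Cohen's d from group summary statistics
#'
#' Same contract as [cohens_d()] but starting from means, SDs and sample
#' sizes (e.g. rows of [summarize_groups()]).
#'
#' @param mean_ref,sd_ref,n_ref reference-group mean, sample SD and size.
#' @param mean_other,sd_other,n_other comparison-group mean, sample SD, size.
#' @return An `effect_size` object.
#' @export
cohens_d_from_stats <- function(mean_ref, sd_ref, n_ref,
                                mean_other, sd_other, n_other) {
  if (n_ref < 2L || n_other < 2L)
    return(new_effect_size(NA_real_, n_ref, n_other, NA_real_, FALSE,
                           "fewer than 2 observations in a group"))
  sp <- sqrt(((n_ref - 1) * sd_ref^2 + (n_other - 1) * sd_other^2) /
               (n_ref + n_other - 2))
  if (sp == 0)
    return(new_effect_size(NA_real_, n_ref, n_other, NA_real_, FALSE,
                           "zero pooled SD denominator"))
  d <- (mean_other - mean_ref) / sp
  new_effect_size(d, n_ref, n_other, d_variance(d, n_ref, n_other), TRUE)
}

#' Large-sample variance of Cohen's d
#'
#' `var(d) = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))`, the canonical
#' large-sample form used for z-comparison of two independent standardized
#' mean differences.
#'
#' @param d Cohen's d (numeric) or an `effect_size` object.
#' @param n1,n2 group sizes (ignored when `d` is an `effect_size`).
#' @return numeric variance (> 0 for finite samples).
#' @export
d_variance <- function(d, n1 = NULL, n2 = NULL) {
  if (inherits(d, "effect_size")) {
    if (!d$defined) stop("effect size is undefined; variance unavailable")
    n1 <- d$n1; n2 <- d$n2; d <- d$d
  }
  if (is.na(d)) stop("effect size is undefined; variance unavailable")
  (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
}

#' Two-sided z-comparison of two independent effect sizes
#'
#' Compares the intervention effect size in the old group with the one in
#' the young group via `z = (d_old - d_young) / sqrt(var_old + var_young)`
#' and a two-sided standard-normal p-value.  `old_larger` is the decision
#' used by the effect-size route of the rate-versus-baseline classifier: the
#' difference must be significant at `alpha` *and* the old-group magnitude
#' must exceed the young-group magnitude.
#'
#' @param young,old `effect_size` objects (young-group and old-group
#'   intervention effects).
#' @param alpha significance level (default 0.05).
#' @return list with `z`, `p`, `old_larger`, `evaluable`.  When either
#'   effect size is undefined the comparison is marked unevaluable and
#'   `z`/`p` are `NA`.
#' @export
compare_effect_sizes <- function(young, old, alpha = .aw_default_alpha) {
  stopifnot(inherits(young, "effect_size"), inherits(old, "effect_size"))
  if (!young$defined || !old$defined)
    return(list(z = NA_real_, p = NA_real_, old_larger = FALSE,
                evaluable = FALSE))
  z <- (old$d - young$d) / sqrt(old$variance + young$variance)
  p <- 2 * pnorm(-abs(z))
  list(z = z, p = p,
       old_larger = (p < alpha) && (abs(old$d) > abs(young$d)),
       evaluable = TRUE)
}
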