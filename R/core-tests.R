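#' One-way between-subjects ANOVA
#'
#' Classic F test of equality of group means (between-subjects factor age in
#' the trajectory stage), fitted via [stats::lm()].
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return An `aw_test` result: `method = "anova1"`, `statistic` (F),
#'   `df = c(k - 1, N - k)`, `p`.
#' @details Degenerate inputs: if every observation is identical the test is
#'   meaningless and an error is raised; if all within-group variances are
#'   zero but means differ, `statistic = Inf` and `p = 0` by convention.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(as.character(groups))
  k <- nlevels(g); n <- length(values)
  if (k < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 2L)) stop("each group needs n >= 2")
  if (n - k < 1L) stop("no residual degrees of freedom")
  if (var(values) == 0) stop("degenerate: all values identical")
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0)
    return(aw_test_result("anova1", Inf, c(k - 1, n - k), 0))
  tab <- anova(lm(values ~ g))
  aw_test_result("anova1", tab$`F value`[1],
                 c(tab$Df[1], tab$Df[2]), tab$`Pr(>F)`[1])
}

#' Fisher's LSD posthoc comparisons against a reference group
#'
#' Unprotected least-significant-difference t tests of every group against
#' the reference, using the pooled one-way mean squared error:
#' `t = (m_g - m_ref) / sqrt(MSE * (1/n_g + 1/n_ref))` on `N - k` degrees of
#' freedom, two-sided, with **no** multiplicity adjustment (the pipeline is
#' built on unadjusted p-values throughout).  Protection comes from gating
#' on the omnibus test, handled by the calling stage.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param reference label of the reference group.
#' @param omnibus optional `aw_test` from [anova_oneway()] on the same data
#'   (carried for bookkeeping; the MSE is recomputed from the data).
#' @return A data.frame (one row per non-reference group, in order of first
#'   appearance): `group`, `diff` (group mean - reference mean), `statistic`
#'   (t), `df`, `p`, `sign` (-1/0/+1 direction of `diff`).  Attribute
#'   `reference` carries the reference label.
#' @details If the MSE is zero, `p = 0` for groups whose mean differs from
#'   the reference and `p = 1` otherwise.
#' @export
fisher_lsd <- function(values, groups, reference, omnibus = NULL) {
  g <- as.character(groups)
  labs <- unique(g)
  if (!reference %in% labs) stop("reference group not present")
  k <- length(labs); n <- length(values)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  df <- n - k
  mse <- ssw / df
  ns <- tapply(values, g, length)
  ms <- tapply(values, g, mean)
  others <- setdiff(labs, reference)
  rows <- lapply(others, function(lab) {
    diff <- unname(ms[lab] - ms[reference])
    if (mse == 0) {
      p <- if (diff == 0) 1 else 0
      tstat <- if (diff == 0) 0 else Inf * sign(diff)
    } else {
      se <- sqrt(mse * (1 / ns[lab] + 1 / ns[reference]))
      tstat <- unname(diff / se)
      p <- 2 * pt(-abs(tstat), df)
    }
    data.frame(group = lab, diff = diff, statistic = tstat, df = df, p = p,
               sign = sign(diff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "method") <- "lsd"
  out
}

#' Kruskal-Wallis omnibus test with Dunn posthoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-square approximation on k - 1 df)
#' followed by Dunn z tests of every group against the reference:
#' `z = (Rbar_g - Rbar_ref) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_g + 1/n_ref))`
#' where `T = sum(t^3 - t)` over tie groups; mid-ranks throughout, two-sided
#' unadjusted p-values.
#'
#' @param values numeric vector (ordinal scores are used as given).
#' @param groups group labels.
#' @param reference label of the reference group.
#' @return list with `omnibus` (`aw_test`, method `"kruskal"`) and
#'   `posthocs` (data.frame `group`, `statistic` (z), `p`, `sign` of the
#'   mean-rank difference; attribute `reference`).
#' @details All values tied: `H = 0`, `p = 1`, every posthoc `p = 1`.
#' @export
kruskal_dunn <- function(values, groups, reference) {
  g <- as.character(groups)
  labs <- unique(g)
  if (length(labs) < 2L) stop("need at least 2 groups")
  if (!reference %in% labs) stop("reference group not present")
  n <- length(values)
  if (var(values) == 0) {
    ph <- data.frame(group = setdiff(labs, reference),
                     statistic = 0, p = 1, sign = 0,
                     stringsAsFactors = FALSE)
    attr(ph, "reference") <- reference
    attr(ph, "method") <- "dunn"
    return(list(
      omnibus = aw_test_result("kruskal", 0, length(labs) - 1, 1),
      posthocs = ph
    ))
  }
  kw <- kruskal.test(values, factor(g))
  omnibus <- aw_test_result("kruskal", unname(kw$statistic),
                            unname(kw$parameter), kw$p.value)
  r <- rank(values)            # mid-ranks
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  base_var <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  others <- setdiff(labs, reference)
  rows <- lapply(others, function(lab) {
    dr <- unname(rbar[lab] - rbar[reference])
    se <- sqrt(base_var * (1 / ns[lab] + 1 / ns[reference]))
    z <- if (se == 0) 0 else dr / se
    data.frame(group = lab, statistic = z, p = 2 * pnorm(-abs(z)),
               sign = sign(dr), stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, rows); rownames(ph) <- NULL
  attr(ph, "reference") <- reference
  attr(ph, "method") <- "dunn"
  list(omnibus = omnibus, posthocs = ph)
}

#' Fisher's exact test on an r x c contingency table with pairwise posthocs
#'
#' Exact conditional test (sum of probabilities of all margin-fixed tables
#' no more probable than the observed one) across all group columns,
#' followed by unadjusted pairwise exact tests of each column against the
#' reference column.  Used for count/category phenotypes (histopathology
#' lesion grades) where means are meaningless.
#'
#' @param counts integer matrix: rows = categories, columns = groups.
#'   Dimnames are used as labels when present.
#' @param reference column name or index of the reference group.
#' @param exact_max_n,exact_max_dim exact enumeration is used when the table
#'   total is at most `exact_max_n` and both dimensions at most
#'   `exact_max_dim` (after zero-margin dropping); larger tables fall back
#'   to a seeded Monte-Carlo p-value.
#' @param mc_b number of Monte-Carlo tables for the fallback.
#' @param seed optional seed for the Monte-Carlo fallback (recorded in the
#'   result's `mc_seed` attribute).
#' @return list with `omnibus` (`aw_test`, method `"fisher_exact"`) and
#'   `posthocs` (data.frame `group`, `p`, `sign`; `sign` is the direction of
#'   the difference in the proportion of the highest category relative to
#'   the reference column).  Zero-margin rows/columns are dropped with a
#'   warning.
#' @export
fisher_exact_table <- function(counts, reference = 1,
                               exact_max_n = 200, exact_max_dim = 4,
                               mc_b = 1e5, seed = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("c", seq_len(nrow(counts)))
  ref_lab <- if (is.numeric(reference)) colnames(counts)[reference] else reference
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns from contingency table")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (!ref_lab %in% colnames(counts)) stop("reference column is empty")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("table degenerate after dropping zero margins")

  exact <- sum(counts) <= exact_max_n &&
    nrow(counts) <= exact_max_dim && ncol(counts) <= exact_max_dim
  mc_seed <- NULL
  if (exact) {
    ft <- fisher.test(counts, workspace = 2e7)
  } else {
    mc_seed <- seed %||% 1L
    ft <- withr::with_seed(mc_seed,
      fisher.test(counts, simulate.p.value = TRUE, B = mc_b))
  }
  omnibus <- aw_test_result("fisher_exact", NA_real_, NULL, ft$p.value)

  top <- nrow(counts)   # highest category carries the direction
  p_top <- counts[top, ] / colSums(counts)
  others <- setdiff(colnames(counts), ref_lab)
  rows <- lapply(others, function(lab) {
    sub <- counts[, c(ref_lab, lab), drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    p <- if (nrow(sub) < 2L) 1 else fisher.test(sub, workspace = 2e7)$p.value
    data.frame(group = lab, p = p,
               sign = sign(unname(p_top[lab] - p_top[ref_lab])),
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, rows); rownames(ph) <- NULL
  attr(ph, "reference") <- ref_lab
  attr(ph, "method") <- "fisher_pairwise"
  out <- list(omnibus = omnibus, posthocs = ph)
  if (!is.null(mc_seed)) attr(out, "mc_seed") <- mc_seed
  out
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test: exact enumeration when both samples are small
#' (`n1 + n2 <= 12`) and tie-free, otherwise the tie-corrected normal
#' approximation without continuity correction (so that for two groups the
#' p-value coincides with the Dunn z test).
#'
#' @param x,y numeric vectors.
#' @return An `aw_test`: `method = "mwu"`, `statistic` (U for `x`), `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (var(c(x, y)) == 0)
    return(aw_test_result("mwu", length(x) * length(y) / 2, NULL, 1))
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  aw_test_result("mwu", unname(wt$statistic), NULL, wt$p.value)
}
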