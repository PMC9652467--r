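#' Omnibus age-sensitivity test for one phenotype
#'
#' Stage-1 dispatch for a single phenotype measured across the age groups
#' of a cross-sectional cohort: continuous phenotypes get a one-way ANOVA
#' with Fisher's LSD posthocs, ordinal phenotypes a Kruskal-Wallis test
#' with Dunn posthocs, and count/category phenotypes Fisher's exact test
#' with pairwise exact tests, always comparing against the youngest
#' (reference) age group.  A phenotype is called age-sensitive when the
#' omnibus p-value falls below `alpha`.
#'
#' @param data data.frame with columns `age_months` (numeric) and `value`
#'   for one phenotype.
#' @param scale one of `"continuous"`, `"ordinal"`, `"count_category"`.
#' @param reference_age numeric age (months) of the reference group
#'   (default: youngest present).
#' @param alpha significance level.
#' @param gate if `TRUE` (default) posthoc p-values are reported only when
#'   the omnibus test is significant (they are still computed internally —
#'   the onset rule needs them only in that case); `FALSE` reports them
#'   unconditionally for diagnostics.
#' @return list: `omnibus` (`aw_test`), `posthocs` (data.frame with one row
#'   per non-reference age, ascending; columns `age_months`, `p`, `sign`),
#'   `age_sensitive` (logical), `gated` (logical: posthocs suppressed).
#' @export
classify_age_sensitivity <- function(data, scale,
                                     reference_age = NULL,
                                     alpha = .aw_default_alpha,
                                     gate = TRUE) {
  stopifnot(all(c("age_months", "value") %in% names(data)))
  scale <- match.arg(scale, c("continuous", "ordinal", "count_category"))
  ages <- sort(unique(data$age_months))
  if (length(ages) < 2L) stop("need at least two age groups")
  ref <- reference_age %||% ages[1]
  if (!ref %in% ages) stop("missing reference group")
  lab <- as.character(data$age_months)
  ref_lab <- as.character(ref)

  if (scale == "continuous") {
    omnibus <- anova_oneway(data$value, lab)
    ph <- fisher_lsd(data$value, lab, ref_lab, omnibus)
  } else if (scale == "ordinal") {
    kd <- kruskal_dunn(data$value, lab, ref_lab)
    omnibus <- kd$omnibus
    ph <- kd$posthocs
  } else {
    tab <- table(factor(data$value), factor(lab, levels = as.character(ages)))
    fe <- fisher_exact_table(tab, reference = ref_lab)
    omnibus <- fe$omnibus
    ph <- fe$posthocs
  }
  ph_out <- data.frame(age_months = as.numeric(ph$group),
                       p = ph$p, sign = ph$sign)
  ph_out <- ph_out[order(ph_out$age_months), , drop = FALSE]
  rownames(ph_out) <- NULL
  age_sensitive <- is.finite(omnibus$p) && omnibus$p < alpha
  gated <- gate && !age_sensitive
  if (gated) ph_out$p <- NA_real_
  list(omnibus = omnibus, posthocs = ph_out,
       age_sensitive = age_sensitive, gated = gated,
       reference_age = ref)
}

#' Age at first detectable change
#'
#' Applies the onset pattern rule to the posthoc p-values of a phenotype's
#' comparisons against the young reference: scanning candidate onset ages
#' in ascending order, age `m` qualifies when (a) every comparison at an
#' age younger than `m` is non-significant (no exception allowed), (b) the
#' comparison at `m` itself is significant, and (c) at most one comparison
#' at an age older than `m` is non-significant (the single allowed
#' exception).  The first qualifying age wins; a significant omnibus with
#' no qualifying age (e.g. a midlife peak that recovers in old age) is
#' classed `"other"`, and a non-significant omnibus is `"none"`.
#'
#' @param posthoc_p named numeric vector of posthoc p-values, names = the
#'   candidate onset ages in months (ascending), e.g.
#'   `c("5" = .3, "8" = .01, ...)`.
#' @param omnibus_significant logical: was the global age test significant?
#' @param alpha significance level.
#' @return list: `onset` (character: `"m<age>"`, `"other"` or `"none"`),
#'   `exception_used` (logical: the qualifying age needed its one allowed
#'   later exception).
#' @export
assign_onset <- function(posthoc_p, omnibus_significant,
                         alpha = .aw_default_alpha) {
  if (length(posthoc_p) < 1L || any(is.na(posthoc_p)))
    stop("incomplete posthoc set")
  ages <- as.numeric(names(posthoc_p))
  if (any(is.na(ages))) stop("posthoc_p must be named by age in months")
  o <- order(ages); ages <- ages[o]; posthoc_p <- posthoc_p[o]
  if (!omnibus_significant)
    return(list(onset = "none", exception_used = FALSE))
  sig <- posthoc_p < alpha
  for (i in seq_along(ages)) {
    earlier_ok <- if (i == 1L) TRUE else all(!sig[seq_len(i - 1L)])
    at_ok <- sig[i]
    later <- if (i == length(ages)) logical(0) else sig[(i + 1L):length(ages)]
    later_ns <- sum(!later)
    if (earlier_ok && at_ok && later_ns <= 1L)
      return(list(onset = paste0("m", ages[i]),
                  exception_used = later_ns == 1L))
  }
  list(onset = "other", exception_used = FALSE)
}

#' Summary of a set of trajectory calls
#'
#' Counts and percentages of age-sensitive phenotypes (ASPs) and of the
#' onset categories among ASPs.  Percentages are rounded half-up to one
#' decimal, matching the convention used when such tables are printed.
#'
#' @param calls data.frame of per-phenotype calls as produced by
#'   [run_trajectory_study()] (needs columns `age_sensitive`, `onset`).
#' @return list: `n_phenotypes`, `n_asp`, `pct_asp`, `onsets` (data.frame
#'   `onset`, `n`, `pct_of_asp`, ordered by age with `"other"` last).
#' @export
summarize_trajectories <- function(calls) {
  if (nrow(calls) == 0L) stop("no calls")
  n <- nrow(calls)
  asp <- calls[calls$age_sensitive, , drop = FALSE]
  n_asp <- nrow(asp)
  onset_levels <- unique(asp$onset)
  num <- suppressWarnings(as.numeric(sub("^m", "", onset_levels)))
  onset_levels <- onset_levels[order(is.na(num), num)]
  tab <- table(factor(asp$onset, levels = onset_levels))
  onsets <- data.frame(onset = names(tab), n = as.integer(tab),
                       pct_of_asp = if (n_asp > 0)
                         round_half_up(100 * as.integer(tab) / n_asp, 1)
                       else numeric(length(tab)),
                       stringsAsFactors = FALSE)
  list(n_phenotypes = n, n_asp = n_asp,
       pct_asp = round_half_up(100 * n_asp / n, 1),
       onsets = onsets)
}
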