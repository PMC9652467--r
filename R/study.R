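#' Wide animals-by-phenotypes matrix of the continuous phenotypes
#'
#' @param table a phenotype table.
#' @return numeric matrix, rows = animals (rownames), columns = continuous
#'   phenotypes; absent measurements are `NA`.
#' @export
phenotype_matrix <- function(table) {
  cont <- table[table$scale == "continuous", , drop = FALSE]
  if (nrow(cont) == 0L) stop("no continuous phenotypes")
  animals <- unique(cont$animal_id)
  phens <- unique(cont$phenotype_id)
  m <- matrix(NA_real_, length(animals), length(phens),
              dimnames = list(animals, phens))
  m[cbind(match(cont$animal_id, animals),
          match(cont$phenotype_id, phens))] <- cont$value
  m
}

#' Run a trajectory (baseline) study
#'
#' Stage 1 of the pipeline over a whole cross-sectional cohort: for every
#' phenotype, the scale-appropriate omnibus test and posthocs against the
#' young reference ([classify_age_sensitivity()]), the onset rule
#' ([assign_onset()]), and the cohort summary
#' ([summarize_trajectories()]).  When at least two continuous phenotypes
#' are present a PCA of the (imputed, standardized) wide matrix is
#' attached.
#'
#' @param table validated phenotype table (single-arm, multi-age).
#' @param config an `aw_config` (see [study_config()]).
#' @param pca run the PCA step (default TRUE).
#' @return list of class `aw_trajectory_study`: `calls` (one row per
#'   phenotype: id, scale, omnibus method/statistic/p, `age_sensitive`,
#'   `onset`, `exception_used`, posthoc p's as `p_m<age>` columns),
#'   `summary`, `pca` (an `aw_pca` or `NULL`), `imputation` (report or
#'   `NULL`), `config`.
#' @export
run_trajectory_study <- function(table, config = study_config(), pca = TRUE) {
  if (nrow(table) == 0L) stop("empty table")
  ids <- unique(table$phenotype_id)
  non_ref_ages <- setdiff(sort(unique(table$age_months)),
                          config$reference_age)
  rows <- lapply(ids, function(id) {
    sl <- table[table$phenotype_id == id, , drop = FALSE]
    scale <- sl$scale[1]
    cl <- tryCatch(
      classify_age_sensitivity(sl, scale,
                               reference_age = config$reference_age,
                               alpha = config$alpha,
                               gate = FALSE),
      error = function(e) stop("phenotype ", id, ": ", conditionMessage(e)))
    pp <- setNames(cl$posthocs$p, as.character(cl$posthocs$age_months))
    on <- assign_onset(pp, cl$age_sensitive, config$alpha)
    out <- data.frame(
      phenotype_id = id, scale = scale, method = cl$omnibus$method,
      statistic = cl$omnibus$statistic, p = cl$omnibus$p,
      age_sensitive = cl$age_sensitive, onset = on$onset,
      exception_used = on$exception_used, stringsAsFactors = FALSE)
    show_ph <- !config$gate_posthocs || cl$age_sensitive
    for (a in non_ref_ages)
      out[[paste0("p_m", a)]] <-
        if (show_ph) unname(pp[as.character(a)]) else NA_real_
    out
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  pca_res <- NULL; imp_rep <- NULL
  n_cont <- length(unique(table$phenotype_id[table$scale == "continuous"]))
  if (pca && n_cont >= 2L) {
    m <- phenotype_matrix(table)
    if (anyNA(m)) {
      imp <- impute_chained(m, seed = config$seed)
      m <- imp$completed
      imp_rep <- imp$report
    }
    pca_res <- pca_phenotypes(m, standardize = TRUE)
  }
  structure(list(calls = calls, summary = summarize_trajectories(calls),
                 pca = pca_res, imputation = imp_rep, config = config),
            class = "aw_trajectory_study")
}

#' Run an intervention (2x2) study
#'
#' Stage 2 (+3) of the pipeline over a young/old by control/treated
#' cohort: per-phenotype factorial fits and effect sizes
#' ([fit_phenotype()]), the countered/accentuated direction call
#' ([classify_direction()]), both rate-versus-baseline model routes,
#' category fractions per route, per-category young-versus-old
#' effect-size concordance, and the standardized-coefficient forest table
#' for continuous phenotypes.  Trajectory calls from a baseline study
#' may be supplied to annotate each phenotype with its age at first
#' detectable change.
#'
#' @param table validated phenotype table restricted to one 2x2 study.
#' @param config an `aw_config`.
#' @param baseline_calls optional trajectory calls data.frame for
#'   [annotate_with_baseline_onsets()].
#' @return list of class `aw_intervention_study`: `calls` (one row per
#'   phenotype with all p-values, effect sizes, z comparison and labels),
#'   `fractions` (list with `interaction` and `effectsize`
#'   `aw_fractions`), `route_disagreement` (count of countered ASPs
#'   labelled differently by the two routes), `concordance` (list by
#'   category, `NULL` where fewer than 3 pairs), `forest`, `config`.
#' @export
run_intervention_study <- function(table, config = study_config(),
                                   baseline_calls = NULL) {
  if (nrow(table) == 0L) stop("empty table")
  ids <- unique(table$phenotype_id)
  alpha <- config$alpha
  rows <- lapply(ids, function(id) {
    sl <- table[table$phenotype_id == id, , drop = FALSE]
    fit <- tryCatch(
      fit_phenotype(sl, sl$scale[1], alpha = alpha,
                    ss_type = config$ss_type),
      error = function(e) stop("phenotype ", id, ": ", conditionMessage(e)))
    dir <- classify_direction(fit, alpha)
    data.frame(
      phenotype_id = id, scale = fit$scale,
      p_age = fit$p_age, p_intervention = fit$p_intervention,
      p_interaction = fit$p_interaction,
      d_age = if (fit$d_age$defined) fit$d_age$d else NA_real_,
      d_treat_young = if (fit$d_treat_young$defined)
        fit$d_treat_young$d else NA_real_,
      d_treat_old = if (fit$d_treat_old$defined)
        fit$d_treat_old$d else NA_real_,
      d_young_defined = fit$d_treat_young$defined,
      d_old_defined = fit$d_treat_old$defined,
      z = fit$comparison$z, p_z = fit$comparison$p,
      old_larger = fit$comparison$old_larger,
      is_asp = dir$is_asp,
      intervention_sensitive =
        (is.finite(fit$p_intervention) && fit$p_intervention < alpha) ||
        (is.finite(fit$p_interaction) && fit$p_interaction < alpha),
      direction = dir$direction,
      model_interaction_route =
        classify_model_interaction_route(fit, dir$direction, alpha),
      model_effectsize_route =
        classify_model_effectsize_route(fit, dir$direction),
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  # countered ASPs that cannot carry a model label in a route fall back to
  # the unevaluable bucket inside category_fractions()
  fractions <- list(interaction = category_fractions(calls, "interaction"),
                    effectsize = category_fractions(calls, "effectsize"))
  countered <- calls$is_asp & !is.na(calls$direction) &
    calls$direction == "countered"
  disagree <- sum(countered &
                    calls$model_interaction_route !=
                    calls$model_effectsize_route)
  conc <- list()
  for (cat in c("countered", "accentuated", "intervention_only", "all")) {
    conc[[cat]] <- tryCatch(
      concordance_by_category(calls, cat, icc_type = config$icc_type),
      error = function(e) NULL)
  }
  forest <- if (any(table$scale == "continuous")) forest_table(table)
            else NULL
  if (!is.null(baseline_calls))
    calls <- annotate_with_baseline_onsets(calls, baseline_calls)
  structure(list(calls = calls, fractions = fractions,
                 route_disagreement = disagree, concordance = conc,
                 forest = forest, config = config),
            class = "aw_intervention_study")
}
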