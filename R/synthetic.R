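#' Specification of a synthetic deep-phenotyping cohort
#'
#' Bundles the parameters of the synthetic-cohort generator: the study
#' geometry (age groups, animals per cell), the phenotype scale mix, the
#' aging signal (onset mix, trajectory shape, effect size in noise-SD
#' units) and — for intervention cohorts — the mix of generative
#' intervention models and their effect sizes.  Every random draw flows
#' through the single mandatory `seed`.
#'
#' Effect-size arguments (`effect_age`, `baseline_shift`, `combined_shift`,
#' `accent_shift`) may be a single number or a length-2 range, in which
#' case each phenotype draws its magnitude uniformly from the range.
#' Effects are expressed in units of the residual noise SD for continuous
#' phenotypes, latent-SD units for ordinal phenotypes and log-odds units
#' for count phenotypes.
#'
#' @param n_phenotypes number of phenotypes to simulate.
#' @param seed integer seed (mandatory).
#' @param n_per_cell animals per age group (baseline) or per design cell
#'   (intervention); default 12, a representative deep-phenotyping group
#'   size.
#' @param age_groups ages in months of the cross-sectional baseline design.
#' @param scale_mix probabilities over continuous / ordinal /
#'   count_category scales.
#' @param onset_mix probabilities over onset categories `none`, `m5`,
#'   `m8`, `m14`, `m20`, `m26`, `other` (defaults shaped like a large
#'   baseline phenotyping screen: ~59% age-sensitive with most onsets in
#'   the second year of life).
#' @param shape trajectory shape for step-like onsets: `"step"` (default)
#'   or `"ramp"`; `other` phenotypes always follow the midlife-peak
#'   archetype (rise to a midlife maximum, return to baseline in old age).
#' @param effect_age aging effect size (SD units; default 2).
#' @param age_direction `"random"` (each phenotype drifts up or down with
#'   equal probability) or `"up"`.
#' @param model_mix probabilities over intervention models `null`,
#'   `baseline`, `rate`, `combined`, `accentuate`.
#' @param baseline_shift treatment shift of the baseline model.
#' @param rate_rho fraction of the age-dependent change removed by the
#'   rate model (1 = full prevention).
#' @param combined_shift age-independent component of the combined model
#'   (its rate component uses `rate_rho`).
#' @param accent_shift shift of the accentuating model (same direction as
#'   the age effect).
#' @param treat_sign `"counter"` (baseline shifts oppose the age effect)
#'   or `"random"`.
#' @param noise_sd residual SD of continuous phenotypes.
#' @param young_age,old_age ages (months) of the 2x2 intervention design.
#' @param count_base_p lesion probability of an unaffected count phenotype.
#' @return list of class `aw_synth_spec`.
#' @export
synthetic_spec <- function(n_phenotypes, seed,
                           n_per_cell = 12,
                           age_groups = c(3, 5, 8, 14, 20, 26),
                           scale_mix = c(continuous = 0.6, ordinal = 0.25,
                                         count_category = 0.15),
                           onset_mix = c(none = 0.41, m5 = 0.03, m8 = 0.03,
                                         m14 = 0.15, m20 = 0.21, m26 = 0.05,
                                         other = 0.12),
                           shape = c("step", "ramp"),
                           effect_age = 2,
                           age_direction = c("random", "up"),
                           model_mix = c(null = 0.2, baseline = 0.2,
                                         rate = 0.2, combined = 0.2,
                                         accentuate = 0.2),
                           baseline_shift = 1.5,
                           rate_rho = 1,
                           combined_shift = 1.2,
                           accent_shift = 1.5,
                           treat_sign = c("counter", "random"),
                           noise_sd = 1,
                           young_age = 3, old_age = 20,
                           count_base_p = 0.15) {
  if (missing(seed)) stop("seed is mandatory")
  shape <- match.arg(shape)
  age_direction <- match.arg(age_direction)
  treat_sign <- match.arg(treat_sign)
  check_mix <- function(m, what) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-8)
      stop("invalid mix: ", what, " must be a probability vector")
  }
  check_mix(scale_mix, "scale_mix")
  check_mix(onset_mix, "onset_mix")
  check_mix(model_mix, "model_mix")
  onset_ages <- paste0("m", age_groups[-1])
  if (!all(setdiff(names(onset_mix), c("none", "other")) %in% onset_ages))
    stop("onset_mix names must match the non-reference age groups")
  structure(
    list(n_phenotypes = n_phenotypes, seed = as.integer(seed),
         n_per_cell = n_per_cell, age_groups = age_groups,
         scale_mix = scale_mix, onset_mix = onset_mix, shape = shape,
         effect_age = effect_age, age_direction = age_direction,
         model_mix = model_mix, baseline_shift = baseline_shift,
         rate_rho = rate_rho, combined_shift = combined_shift,
         accent_shift = accent_shift, treat_sign = treat_sign,
         noise_sd = noise_sd, young_age = young_age, old_age = old_age,
         count_base_p = count_base_p),
    class = "aw_synth_spec"
  )
}

draw_magnitude <- function(par) {
  if (length(par) == 2L) runif(1, par[1], par[2]) else par
}

# mean trajectory over the study ages for one phenotype
trajectory_mean <- function(ages, onset, shape, delta) {
  k <- length(ages)
  if (onset == "none") return(rep(0, k))
  if (onset == "other") {
    # midlife-peak archetype: flat at the reference age, rise to a plateau
    # around the middle of life, back to baseline in the oldest groups
    w <- numeric(k)
    mid <- ceiling(k / 2)
    if (mid >= 2) w[2:mid] <- seq_len(mid - 1) / (mid - 1)
    if (mid + 1 <= k) w[mid + 1] <- 1
    if (mid + 2 <= k) w[(mid + 2):k] <- 0
    if (k == 6) w <- c(0, 0.5, 1, 1, 0, 0)   # canonical six-age layout
    return(delta * w)
  }
  onset_age <- as.numeric(sub("^m", "", onset))
  if (shape == "step") {
    delta * as.numeric(ages >= onset_age)
  } else {              # ramp: linear rise from the onset age to the oldest
    idx <- which(ages >= onset_age)
    w <- numeric(k)
    w[idx] <- seq_along(idx) / length(idx)
    delta * w
  }
}

draw_values <- function(n, mu, scale, noise_sd, count_base_p) {
  switch(scale,
    continuous = rnorm(n, mu, noise_sd),
    ordinal = {
      latent <- rnorm(n, mu, 1)
      cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))   # equal-probability under null
      as.numeric(findInterval(latent, cuts) + 1L)
    },
    count_category = as.numeric(
      rbinom(n, 1, plogis(qlogis(count_base_p) + mu)))
  )
}

#' Generate a cross-sectional baseline cohort with known ground truth
#'
#' Simulates a multi-age-group deep-phenotyping study: each phenotype gets
#' a scale, an onset category, a trajectory shape and an aging effect
#' size, and every animal of every age group receives one measurement.
#' All phenotypes are measured on the same animals (one animal set per
#' cohort), so the wide matrix needed for PCA is well defined.
#'
#' @param spec an `aw_synth_spec`.
#' @return list: `table` (long phenotype table, see
#'   [read_phenotype_table()] for the column contract) and `truth`
#'   (data.frame: `phenotype_id`, `scale`, `onset`, `shape`, `direction`,
#'   `effect`, `true_d_oldest` — the population effect at the oldest age
#'   in noise-SD units).
#' @export
generate_baseline_cohort <- function(spec) {
  stopifnot(inherits(spec, "aw_synth_spec"))
  ages <- spec$age_groups
  n <- spec$n_per_cell
  animal_ids <- sprintf("a%03d", seq_len(length(ages) * n))
  age_of_animal <- rep(ages, each = n)
  withr::with_seed(spec$seed, {
    rows <- vector("list", spec$n_phenotypes)
    truth <- vector("list", spec$n_phenotypes)
    for (i in seq_len(spec$n_phenotypes)) {
      id <- sprintf("p%04d", i)
      scale <- sample(names(spec$scale_mix), 1, prob = spec$scale_mix)
      onset <- sample(names(spec$onset_mix), 1, prob = spec$onset_mix)
      shape <- if (onset == "other") "midlife_peak"
               else if (onset == "none") "null" else spec$shape
      dir <- if (spec$age_direction == "up") 1 else sample(c(-1, 1), 1)
      delta <- draw_magnitude(spec$effect_age)
      mu <- dir * trajectory_mean(ages, onset, spec$shape, delta)
      vals <- unlist(lapply(seq_along(ages), function(k)
        draw_values(n, mu[k], scale, spec$noise_sd, spec$count_base_p)))
      rows[[i]] <- data.frame(
        animal_id = animal_ids, phenotype_id = id, scale = scale,
        age_group = paste0("m", age_of_animal),
        age_months = age_of_animal, arm = "control", value = vals,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        phenotype_id = id, scale = scale, onset = onset, shape = shape,
        direction = dir, effect = if (onset == "none") 0 else delta,
        true_d_oldest = mu[length(ages)] / spec$noise_sd,
        stringsAsFactors = FALSE)
    }
  })
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a 2x2 intervention cohort with known ground truth
#'
#' Simulates a young/old by control/treated study.  Every phenotype is
#' age-sensitive (it carries the aging effect of the spec) and draws an
#' intervention model from `model_mix`:
#'
#' * `null`: treatment changes nothing;
#' * `baseline`: an age-independent shift applied equally at both ages;
#' * `rate`: the age-dependent change is reduced by `rate_rho` in treated
#'   old animals, with no effect in treated young;
#' * `combined`: both of the above (old effect strictly larger);
#' * `accentuate`: a shift in the *same* direction as the age effect.
#'
#' @param spec an `aw_synth_spec`.
#' @return list: `table` (long phenotype table with `age_group` in
#'   `young`/`old` and both arms) and `truth` (data.frame: `phenotype_id`,
#'   `scale`, `model`, `direction`, plus population contrasts
#'   `true_d_age`, `true_d_treat_young`, `true_d_treat_old` in noise-SD
#'   units).
#' @export
generate_intervention_cohort <- function(spec) {
  stopifnot(inherits(spec, "aw_synth_spec"))
  n <- spec$n_per_cell
  cells <- expand.grid(age_group = c("young", "old"),
                       arm = c("control", "treated"),
                       stringsAsFactors = FALSE)
  animal_ids <- sprintf("a%03d", seq_len(4L * n))
  cell_of_animal <- cells[rep(seq_len(4L), each = n), ]
  withr::with_seed(spec$seed, {
    rows <- vector("list", spec$n_phenotypes)
    truth <- vector("list", spec$n_phenotypes)
    for (i in seq_len(spec$n_phenotypes)) {
      id <- sprintf("p%04d", i)
      scale <- sample(names(spec$scale_mix), 1, prob = spec$scale_mix)
      model <- sample(names(spec$model_mix), 1, prob = spec$model_mix)
      dir <- if (spec$age_direction == "up") 1 else sample(c(-1, 1), 1)
      delta <- draw_magnitude(spec$effect_age)
      s_dir <- if (spec$treat_sign == "counter") -dir else sample(c(-1, 1), 1)
      mu_yc <- 0
      mu_oc <- dir * delta
      mus <- switch(model,
        null = c(yt = 0, ot = mu_oc),
        baseline = {
          s <- s_dir * draw_magnitude(spec$baseline_shift)
          c(yt = s, ot = mu_oc + s)
        },
        rate = c(yt = 0, ot = dir * delta * (1 - spec$rate_rho)),
        combined = {
          s <- -dir * draw_magnitude(spec$combined_shift)
          c(yt = s, ot = dir * delta * (1 - spec$rate_rho) + s)
        },
        accentuate = {
          s <- dir * draw_magnitude(spec$accent_shift)
          c(yt = s, ot = mu_oc + s)
        })
      mu_cell <- c(young_control = mu_yc, old_control = mu_oc,
                   young_treated = unname(mus["yt"]),
                   old_treated = unname(mus["ot"]))
      key <- paste(cell_of_animal$age_group, cell_of_animal$arm, sep = "_")
      vals <- numeric(length(key))
      for (cl in names(mu_cell)) {
        idx <- key == cl
        vals[idx] <- draw_values(sum(idx), mu_cell[cl], scale,
                                 spec$noise_sd, spec$count_base_p)
      }
      rows[[i]] <- data.frame(
        animal_id = animal_ids, phenotype_id = id, scale = scale,
        age_group = cell_of_animal$age_group,
        age_months = ifelse(cell_of_animal$age_group == "young",
                            spec$young_age, spec$old_age),
        arm = cell_of_animal$arm, value = vals,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        phenotype_id = id, scale = scale, model = model, direction = dir,
        true_d_age = (mu_cell["old_control"] - mu_cell["young_control"]) /
          spec$noise_sd,
        true_d_treat_young = (mu_cell["young_treated"] -
                                mu_cell["young_control"]) / spec$noise_sd,
        true_d_treat_old = (mu_cell["old_treated"] -
                              mu_cell["old_control"]) / spec$noise_sd,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  })
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Write / read ground truth as JSON
#'
#' Lossless round-trip of a generator truth table, with a schema tag so
#' stale files fail loudly.
#'
#' @param truth data.frame from a generator.
#' @param path file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the truth data.frame.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(schema = "agewise-ground-truth-v1", phenotypes = truth),
    path, dataframe = "rows", digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "agewise-ground-truth-v1"))
    stop("not an agewise ground-truth file (schema mismatch)")
  df <- as.data.frame(obj$phenotypes, stringsAsFactors = FALSE)
  df
}
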