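#' Young-versus-old effect-size concordance within a call category
#'
#' Collects the `(d_treat_young, d_treat_old)` pairs of the phenotypes in
#' the selected category of an intervention study's calls table and
#' delegates to [concordance()].  Pairs with an undefined effect size on
#' either side are dropped.
#'
#' @param calls calls data.frame from [run_intervention_study()] (columns
#'   `direction`, `d_treat_young`, `d_treat_old`, `d_young_defined`,
#'   `d_old_defined`, `is_asp`).
#' @param category `"countered"`, `"accentuated"`,
#'   `"intervention_only"` (intervention-sensitive but not age-sensitive)
#'   or `"all"` (every phenotype with both effect sizes defined).
#' @param ... passed to [concordance()].
#' @return an `aw_concordance` object.
#' @export
concordance_by_category <- function(calls,
                                    category = c("countered", "accentuated",
                                                 "intervention_only", "all"),
                                    ...) {
  category <- match.arg(category)
  keep <- switch(category,
    countered = calls$is_asp & !is.na(calls$direction) &
      calls$direction == "countered",
    accentuated = calls$is_asp & !is.na(calls$direction) &
      calls$direction == "accentuated",
    intervention_only = !calls$is_asp & calls$intervention_sensitive,
    all = rep(TRUE, nrow(calls))
  )
  keep <- keep & calls$d_young_defined & calls$d_old_defined
  sub <- calls[keep, , drop = FALSE]
  if (nrow(sub) < 3L) stop("insufficient pairs: need at least 3")
  concordance(sub$d_treat_young, sub$d_treat_old, ...)
}

#' Chained-equation imputation with predictive mean matching
#'
#' Single-imputation variant of multivariate imputation by chained
#' equations: missing entries start at their column means, then for a
#' fixed number of sweeps each incomplete column is regressed on all
#' others (observed rows only) and its missing entries are refreshed with
#' predictive-mean-matched draws from a pool of the `donors` closest
#' observed values.  Observed entries are never altered, and the whole
#' procedure is deterministic given `seed`.
#'
#' @param x numeric matrix (animals x phenotypes), `NA` = missing.
#' @param iterations number of sweeps (default 10).
#' @param seed integer seed driving the donor draws.
#' @param donors size of the predictive-mean-matching donor pool.
#' @return list: `completed` (matrix), `report` (list: `n_missing_filled`,
#'   `iterations`, `seed`, `converged` — largest last-sweep change below
#'   1e-6 of the column SD scale).
#' @export
impute_chained <- function(x, iterations = 10, seed = 1, donors = 5) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (any(colSums(!miss) < 2L)) stop("every column needs >= 2 observed values")
  if (any(colMeans(miss) >= 0.5))
    warning("some columns exceed 50% missingness")
  n_fill <- sum(miss)
  if (n_fill == 0L)
    return(list(completed = x,
                report = list(n_missing_filled = 0L, iterations = 0L,
                              seed = seed, converged = TRUE)))
  comp <- x
  for (j in seq_len(ncol(comp)))
    comp[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
  delta <- Inf
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      prev <- comp[miss]
      for (j in which(colSums(miss) > 0)) {
        obs <- !miss[, j]
        xo <- comp[obs, -j, drop = FALSE]
        yo <- comp[obs, j]
        fit <- lm.fit(cbind(1, xo), yo)
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred_obs <- drop(cbind(1, xo) %*% beta)
        pred_mis <- drop(cbind(1, comp[!obs, -j, drop = FALSE]) %*% beta)
        for (i in seq_along(pred_mis)) {
          pool <- order(abs(pred_obs - pred_mis[i]))[seq_len(min(donors, sum(obs)))]
          comp[which(!obs)[i], j] <- yo[pool[sample.int(length(pool), 1L)]]
        }
      }
      delta <- max(abs(comp[miss] - prev))
    }
  })
  scale_ref <- max(apply(x, 2, sd, na.rm = TRUE), na.rm = TRUE)
  list(completed = comp,
       report = list(n_missing_filled = n_fill, iterations = iterations,
                     seed = seed,
                     converged = is.finite(delta) &&
                       delta <= 1e-6 * max(scale_ref, 1)))
}

#' Principal component analysis of continuous phenotypes
#'
#' Column-standardized PCA (each phenotype z-scored, so the decomposition
#' works on the correlation structure — phenotypes carry wildly different
#' units) with a deterministic sign convention: within each component the
#' largest-magnitude loading is made positive.  Zero-variance columns are
#' dropped with a warning; `min(nrow - 1, ncol)` components are retained.
#'
#' @param x numeric matrix, rows = animals, columns = phenotypes; must be
#'   complete (impute first, see [impute_chained()]).
#' @param standardize scale columns to unit variance (default TRUE).
#' @return list of class `aw_pca`: `scores` (animals x components),
#'   `loadings` (phenotypes x components, orthonormal),
#'   `variance_explained` (fractions, non-increasing), `center`, `scale`.
#' @export
pca_phenotypes <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix has missing values; impute first")
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 variable columns")
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  k <- min(nrow(x) - 1L, ncol(x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  # reference element = first loading within tolerance of the maximum
  # magnitude, so equal-magnitude ties cannot flip with row order
  flip <- apply(rot, 2, function(l) {
    ref <- which(abs(l) >= max(abs(l)) - 1e-8)[1]
    sign(l[ref])
  })
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  sco <- sweep(sco, 2, flip, `*`)
  ve <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  structure(list(scores = sco, loadings = rot, variance_explained = ve,
                 center = pc$center,
                 scale = if (standardize) pc$scale else NULL),
            class = "aw_pca")
}

#' Forest table of standardized coefficients across phenotypes
#'
#' Fits [standardized_lm()] to every continuous phenotype of a 2x2 study
#' table and assembles the age, intervention and interaction coefficients
#' (with their 95% CIs) into one table sorted by the age coefficient —
#' ties broken by phenotype id — so that the same row order serves all
#' three forest-plot panels.
#'
#' @param table a phenotype table (see [read_phenotype_table()]) restricted
#'   to one 2x2 study.
#' @return data.frame, one row per continuous phenotype: `phenotype_id`
#'   plus `<term>_estimate`, `<term>_lo`, `<term>_hi` for the three terms.
#' @export
forest_table <- function(table) {
  cont <- table[table$scale == "continuous", , drop = FALSE]
  if (nrow(cont) == 0L) stop("no continuous phenotypes")
  ids <- unique(cont$phenotype_id)
  rows <- lapply(ids, function(id) {
    sl <- cont[cont$phenotype_id == id, , drop = FALSE]
    co <- standardized_lm(sl$value, sl$age_group, sl$arm)
    out <- data.frame(phenotype_id = id, stringsAsFactors = FALSE)
    for (tm in co$term) {
      r <- co[co$term == tm, ]
      out[[paste0(tm, "_estimate")]] <- r$estimate
      out[[paste0(tm, "_lo")]] <- r$ci_lo
      out[[paste0(tm, "_hi")]] <- r$ci_hi
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_estimate, out$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
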