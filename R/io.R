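.aw_scales <- c("continuous", "ordinal", "count_category")
.aw_table_cols <- c("animal_id", "phenotype_id", "scale", "age_group",
                    "age_months", "arm", "value")

#' Read a long-format phenotype table
#'
#' The universal input of the pipeline: one row per (animal, phenotype)
#' measurement with columns `animal_id`, `phenotype_id`, `scale`
#' (continuous / ordinal / count_category), `age_group` (text label),
#' `age_months` (numeric), `arm` (control / treated) and `value`.
#' Violations are reported with row numbers.
#'
#' @param path TSV or CSV file (delimiter sniffed from the header line);
#'   lines starting with `#` are treated as comments.
#' @return validated data.frame.
#' @export
read_phenotype_table <- function(path) {
  header <- readLines(path, n = 50L)
  header <- header[!startsWith(header, "#")][1]
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_phenotype_table(df)
}

#' @rdname read_phenotype_table
#' @param df a data.frame to validate in place.
#' @export
validate_phenotype_table <- function(df) {
  missing_cols <- setdiff(.aw_table_cols, names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad_scale <- !df$scale %in% .aw_scales
  if (any(bad_scale))
    stop("unknown scale token at row(s) ",
         paste(head(which(bad_scale), 5), collapse = ", "),
         ": ", paste(unique(df$scale[bad_scale]), collapse = ", "))
  key <- paste(df$animal_id, df$phenotype_id)
  if (anyDuplicated(key) > 0)
    stop("duplicate (animal_id, phenotype_id) at row(s) ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))
  sc <- tapply(df$scale, df$phenotype_id, function(s) length(unique(s)))
  if (any(sc > 1))
    stop("scale not constant within phenotype(s): ",
         paste(head(names(sc)[sc > 1], 5), collapse = ", "))
  if (!is.numeric(df$age_months)) stop("age_months must be numeric")
  if (!is.numeric(df$value)) stop("value must be numeric")
  df
}

#' Write a phenotype table (or any result table) as commented TSV
#'
#' Tab-separated, UTF-8, `.` decimal mark, `NA` for missing, preceded by
#' `#`-prefixed header lines recording the package version and any extra
#' metadata, so every output is self-describing.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta optional named character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(df, path, meta = NULL) {
  hdr <- c(sprintf("# agewise %s", as.character(utils::packageVersion("agewise"))),
           sprintf("# written %s", format(Sys.time(), "%Y-%m-%d")),
           if (!is.null(meta)) sprintf("# %s: %s", names(meta), meta))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Study configuration
#'
#' Central knob collection with the pipeline defaults: significance level
#' 0.05 with unadjusted p-values throughout, ages 3/5/8/14/20/26 months
#' with the 3-month group as reference, Type II sums of squares for
#' factorial fits, absolute-agreement single-rater ICC, round-half-up
#' percentages to one decimal, posthoc gating on the omnibus test.
#'
#' @param alpha significance level.
#' @param age_groups ages (months) of the trajectory design.
#' @param reference_age reference age (months).
#' @param ss_type `"II"` or `"I"` factorial sums of squares.
#' @param icc_type `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @param gate_posthocs report posthocs only under a significant omnibus.
#' @param seed seed for any seeded sub-procedure (Monte-Carlo exact tests,
#'   imputation draws).
#' @return list of class `aw_config`.
#' @export
study_config <- function(alpha = 0.05,
                         age_groups = c(3, 5, 8, 14, 20, 26),
                         reference_age = 3,
                         ss_type = "II",
                         icc_type = "ICC2",
                         gate_posthocs = TRUE,
                         seed = 1L) {
  stopifnot(reference_age %in% age_groups)
  structure(list(alpha = alpha, age_groups = age_groups,
                 reference_age = reference_age, ss_type = ss_type,
                 icc_type = icc_type, gate_posthocs = gate_posthocs,
                 seed = as.integer(seed)),
            class = "aw_config")
}
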