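#!/usr/bin/env Rscript
# Stage 1: classify every phenotype of the simulated baseline cohort as
# age-sensitive or not, assign ages at first detectable change, and
# summarize the onset distribution; run the cohort-level PCA.
# Requires: analysis/01_simulate_cohorts.R.

suppressPackageStartupMessages(library(agewise))

table <- read_phenotype_table("results/baseline_table.tsv")
truth <- read_ground_truth("results/baseline_truth.json")

study <- run_trajectory_study(table, study_config(seed = 20260926L))

write_phenotype_table(study$calls, "results/trajectory_calls.tsv",
                      meta = c(stage = "trajectory calls"))
jsonlite::write_json(study$summary, "results/trajectory_summary.json",
                     auto_unbox = TRUE, digits = NA)
write_phenotype_table(
  data.frame(animal_id = rownames(study$pca$scores),
             round(study$pca$scores[, 1:2], 4)),
  "results/trajectory_pca_scores.tsv", meta = c(stage = "PCA scores"))

s <- study$summary
cat(sprintf("%d of %d phenotypes (%.1f%%) called age-sensitive.\n",
            s$n_asp, s$n_phenotypes, s$pct_asp))
cat("Onset distribution among ASPs:\n")
print(s$onsets)
agree <- mean(study$calls$onset == truth$onset[
  match(study$calls$phenotype_id, truth$phenotype_id)])
cat(sprintf("Agreement with generative ground truth: %.1f%%\n", 100 * agree))
cat(sprintf("PCA: first two components explain %.1f%% and %.1f%% of variance.\n",
            100 * study$pca$variance_explained[1],
            100 * study$pca$variance_explained[2]))
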