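#!/usr/bin/env Rscript
# Simulate the two study types the pipeline analyzes: a six-age-group
# baseline cohort (222 phenotypes, mixed scales, onset mix shaped like a
# large deep-phenotyping screen) and a 2x2 young/old x control/treated
# intervention cohort (206 phenotypes, mixed intervention models).
# Outputs: long tables (TSV) and ground truth (JSON) under results/.

suppressPackageStartupMessages(library(agewise))
dir.create("results", showWarnings = FALSE)

seed <- 20260926L

base_spec <- synthetic_spec(
  n_phenotypes = 222, seed = seed, n_per_cell = 12,
  effect_age = c(1.5, 3))
baseline <- generate_baseline_cohort(base_spec)
write_phenotype_table(baseline$table, "results/baseline_table.tsv",
                      meta = c(study = "synthetic baseline cohort",
                               seed = seed))
write_ground_truth(baseline$truth, "results/baseline_truth.json")

int_spec <- synthetic_spec(
  n_phenotypes = 206, seed = seed + 1L, n_per_cell = 12,
  effect_age = c(1.5, 3),
  model_mix = c(null = 0.35, baseline = 0.3, rate = 0.1, combined = 0.1,
                accentuate = 0.15))
intervention <- generate_intervention_cohort(int_spec)
write_phenotype_table(intervention$table, "results/intervention_table.tsv",
                      meta = c(study = "synthetic intervention cohort",
                               seed = seed + 1L))
write_ground_truth(intervention$truth, "results/intervention_truth.json")

cat(sprintf(
  "Simulated %d baseline phenotypes (%d animals) and %d intervention phenotypes (%d animals).\n",
  222, length(unique(baseline$table$animal_id)),
  206, length(unique(intervention$table$animal_id))))
cat("Generative onset mix of the baseline cohort:\n")
print(table(baseline$truth$onset))
cat("Generative intervention-model mix:\n")
print(table(intervention$truth$model))
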