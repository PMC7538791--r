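## Shared study design for the analysis scripts: one generative world and
## three cohorts drawn from it (training, tuning, held-out validation),
## mirroring a multi-dataset train/tune/validate design at desk scale.
## Sourced by the numbered scripts; everything is deterministic from these
## seeds.

library(reosig)

WORLD_SEED <- 2026L
F_STABLE <- 0.85

study_cohorts <- function() {
  list(
    train = generate_cohort(simulation_config(seed = WORLD_SEED, sample_seed = 101L)),
    tune = generate_cohort(simulation_config(
      n_cancer = 6L, n_adjacent = 0L, n_healthy = 6L, n_pancreatitis = 0L,
      seed = WORLD_SEED, sample_seed = 102L)),
    held = generate_cohort(simulation_config(
      n_cancer = 75L, n_adjacent = 25L, n_healthy = 50L, n_pancreatitis = 50L,
      seed = WORLD_SEED, sample_seed = 103L)))
}

results_path <- function(file) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", file)
}

write_tsv <- function(df, file) {
  utils::write.table(df, results_path(file), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote results/", file)
}
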