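#!/usr/bin/env Rscript
## Step 1 — build the synthetic study cohorts and record their design.
##
## Three cohorts are drawn from one generative world (2,000 genes, 50
## planted reversal pairs, penetrance 0.95, log-noise SD 0.3): a 160-sample
## training cohort (60 cancer + 20 cancer-adjacent vs 40 healthy + 40
## pancreatitis), a 12-sample tuning cohort (6 cancer vs 6 healthy), and a
## 200-sample held-out validation cohort.

source("analysis/study_design.R")

sets <- study_cohorts()

summary <- do.call(rbind, lapply(names(sets), function(nm) {
  co <- sets[[nm]]$cohort
  data.frame(cohort = nm,
             n_genes = nrow(co$matrix),
             n_samples = ncol(co$matrix),
             n_cancer = sum(co$clinical == "CANCER"),
             n_adjacent = sum(co$clinical == "CANCER_ADJACENT"),
             n_healthy = sum(co$clinical == "HEALTHY_NORMAL"),
             n_pancreatitis = sum(co$clinical == "PANCREATITIS"))
}))
print(summary, row.names = FALSE)
write_tsv(summary, "cohort_summary.tsv")
write_tsv(sets$train$truth$planted_pairs, "planted_pairs.tsv")

message(sprintf("world seed %d: %d planted reversal pairs over %d genes",
                WORLD_SEED, nrow(sets$train$truth$planted_pairs),
                nrow(sets$train$cohort$matrix)))
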