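#!/usr/bin/env Rscript
## Step 4 — apply the frozen signature to the held-out cohort and report
## confusion metrics and the rank-sum AUC with its bootstrap interval.

source("analysis/study_design.R")

sets <- study_cohorts()
held <- sets$held

sig <- read_signature(results_path("signature.tsv"))
calls <- classify_cohort(held$cohort$matrix, sig)
calls$truth <- unname(held$cohort$binary[calls$sample_id])
rep <- evaluate_signature(held$cohort, sig, n_bootstrap = 2000L, seed = 11L)

print(rep)
write_tsv(calls, "heldout_calls.tsv")
write_tsv(data.frame(
  tp = rep$tp, fp = rep$fp, tn = rep$tn, fn = rep$fn,
  sensitivity = rep$sensitivity, specificity = rep$specificity,
  accuracy = rep$accuracy, gmean = rep$gmean,
  auc = rep$auc, auc_ci_low = rep$auc_ci_low, auc_ci_high = rep$auc_ci_high,
  n_bootstrap = rep$n_bootstrap, seed = rep$seed), "evaluation.tsv")
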