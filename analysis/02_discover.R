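#!/usr/bin/env Rscript
## Step 2 — mine stable pairs per class and intersect them into reversal
## gene pairs (RGPs).
##
## Stable pairs are oriented orderings held in at least 85% of a group's
## samples; the non-tumor set additionally requires the same orientation in
## healthy and pancreatitis samples separately.  An RGP is a pair whose
## stable orientation flips between tumor and non-tumor.  Discoveries are
## judged against the generative ground truth: recovery of the planted
## pairs, and false positives as discoveries whose population orderings do
## not actually reverse.

source("analysis/study_design.R")

sets <- study_cohorts()
train <- sets$train

st <- stable_pairs(binary_projection(train$cohort, "TUMOR"), F_STABLE, "TUMOR")
sn <- stable_nontumor_pairs(
  clinical_projection(train$cohort, "HEALTHY_NORMAL"),
  clinical_projection(train$cohort, "PANCREATITIS"), F_STABLE)
rgps <- reversal_pairs(st, sn)

planted_keys <- paste(train$truth$planted_pairs$gene_a,
                      train$truth$planted_pairs$gene_b)
rgps$planted <- paste(rgps$gene_a, rgps$gene_b) %in% planted_keys
rgps$population_reversal <- true_reversal_status(rgps, train$truth)

summary <- data.frame(
  tumor_stable_pairs = nrow(st$pairs),
  nontumor_stable_pairs = nrow(sn$pairs),
  rgps = nrow(rgps),
  planted_recovered = sum(rgps$planted),
  planted_total = nrow(train$truth$planted_pairs),
  false_reversals = sum(!rgps$population_reversal))
print(summary, row.names = FALSE)
write_tsv(rgps, "rgps.tsv")
write_tsv(summary, "discovery_summary.tsv")

message(sprintf(
  "recovered %d/%d planted pairs; %d discoveries, %d not supported by the population structure",
  summary$planted_recovered, summary$planted_total, summary$rgps,
  summary$false_reversals))
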