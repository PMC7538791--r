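#!/usr/bin/env Rscript
## Step 3 — tune the candidate RGPs, rank them by reversal score, and
## forward-select the minimal best panel.
##
## Candidates must be unanimously consistent in the independent tuning
## cohort.  Survivors are ranked by the reversal score (geometric mean of
## the wrong-sign-zeroed class-mean rank differences), and forward selection
## walks the sorted list, keeping the smallest panel size whose
## strict-majority vote maximizes the geometric mean of sensitivity and
## specificity on the training cohort.

source("analysis/study_design.R")

sets <- study_cohorts()
train <- sets$train

rgps <- utils::read.table(results_path("rgps.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
if (!nrow(rgps)) stop("no RGPs found; run analysis/02_discover.R first")

tuned <- tuning_filter(rgps[, c("gene_a", "gene_b", "tumor_support",
                                "nontumor_support")], sets$tune$cohort)
scored <- sort_by_score(score_reversal_pairs(train$cohort, tuned))
k_max <- min(20L, nrow(scored))
sig <- forward_select(scored, train$cohort, k_max = k_max)

message(sprintf("%d RGPs passed tuning; forward selection over top %d chose k = %d",
                nrow(tuned), k_max, sig$k))
write_tsv(data.frame(k = seq_along(sig$metric_trace), gmean = sig$metric_trace),
          "selection_trace.tsv")
write_tsv(utils::head(scored, k_max), "scored_candidates.tsv")
write_signature(sig, results_path("signature.tsv"))
message("wrote results/signature.tsv")
print(sig)
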