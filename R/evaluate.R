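#' Confusion-matrix metrics of a set of calls
#'
#' Tumor is the positive class.  Sensitivity is the fraction of true tumors
#' called tumor, specificity the fraction of true non-tumors called
#' non-tumor, accuracy the overall fraction correct, and the geometric mean
#' `gmean = sqrt(sensitivity * specificity)` is the balanced summary used
#' for panel selection and reporting.
#'
#' @param calls data.frame from [classify_cohort()] (columns `sample_id`,
#'   `call`), or a character vector of `TUMOR`/`NONTUMOR` calls named by
#'   sample.
#' @param truth character vector of true binary labels named by sample id
#'   (e.g. the `binary` element of a [labeled_cohort()]).
#' @return an object of class `evaluation_report`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`, `gmean`; ROC
#'   fields (`auc`, `auc_ci_low`, `auc_ci_high`, `n_bootstrap`, `seed`) are
#'   `NA` until filled by [roc_auc()]/[evaluate_signature()].
#' @export
confusion_metrics <- function(calls, truth) {
  if (is.data.frame(calls)) {
    cv <- calls$call
    names(cv) <- calls$sample_id
    calls <- cv
  }
  if (is.null(names(calls)) || is.null(names(truth)))
    stop("calls and truth must be named by sample id")
  missing <- setdiff(names(calls), names(truth))
  if (length(missing))
    stop("no truth label for sample(s): ", paste(missing, collapse = ", "))
  truth <- truth[names(calls)]
  stopifnot(all(calls %in% BINARY_LEVELS), all(truth %in% BINARY_LEVELS))
  tp <- sum(calls == "TUMOR" & truth == "TUMOR")
  fn <- sum(calls == "NONTUMOR" & truth == "TUMOR")
  tn <- sum(calls == "NONTUMOR" & truth == "NONTUMOR")
  fp <- sum(calls == "TUMOR" & truth == "NONTUMOR")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         gmean = sqrt(sens * spec),
         auc = NA_real_, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
         n_bootstrap = NA_integer_, seed = NA_integer_),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.4f | specificity %.4f | accuracy %.4f | gmean %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$gmean))
  if (!is.na(x$auc))
    cat(sprintf("  AUC %.4f (%.1f%% bootstrap CI %.4f-%.4f, B=%d, seed=%d)\n",
                x$auc, 95, x$auc_ci_low, x$auc_ci_high, x$n_bootstrap, x$seed))
  invisible(x)
}

## Rank-sum (Mann-Whitney) AUC: probability that a random tumor sample's
## score exceeds a random non-tumor sample's, ties counting one half.
rank_sum_auc <- function(scores, is_tumor) {
  n1 <- sum(is_tumor); n0 <- sum(!is_tumor)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_tumor]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank-sum AUC of vote fractions with a bootstrap confidence interval
#'
#' The AUC is the probability that a randomly chosen tumor sample's vote
#' fraction exceeds a randomly chosen non-tumor sample's, with ties counted
#' one half (the Mann-Whitney formulation; identical to the trapezoidal area
#' under the empirical ROC curve).  The confidence interval is a stratified
#' percentile bootstrap: samples are resampled with replacement within each
#' class, and the 2.5/97.5 percentiles of the resampled AUCs are reported.
#'
#' @param fractions numeric scores (vote fractions) named by sample id.
#' @param truth binary labels (`TUMOR`/`NONTUMOR`) named by sample id.
#' @param n_bootstrap number of bootstrap replicates, default 2000.
#' @param seed integer seed making the interval reproducible.
#' @param conf_level confidence level, default 0.95.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_bootstrap`, `seed`.
#' @export
roc_auc <- function(fractions, truth, n_bootstrap = 2000L, seed = 1L,
                    conf_level = 0.95) {
  if (!is.null(names(fractions)) && !is.null(names(truth)))
    truth <- truth[names(fractions)]
  stopifnot(length(fractions) == length(truth), n_bootstrap >= 1L)
  is_tumor <- truth == "TUMOR"
  if (!any(is_tumor) || all(is_tumor))
    stop("roc_auc needs samples from both classes")
  auc <- rank_sum_auc(fractions, is_tumor)
  idx1 <- which(is_tumor); idx0 <- which(!is_tumor)
  ## bootstrap under its own seed, restoring the caller's RNG state after
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  reps <- vapply(seq_len(n_bootstrap), function(b) {
    i1 <- sample(idx1, length(idx1), replace = TRUE)
    i0 <- sample(idx0, length(idx0), replace = TRUE)
    s <- c(fractions[i1], fractions[i0])
    rank_sum_auc(s, c(rep(TRUE, length(i1)), rep(FALSE, length(i0))))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  list(auc = auc, ci_low = min(ci[1L], auc), ci_high = max(ci[2L], auc),
       n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed))
}

#' Sensitivity and specificity at a vote-fraction cutoff
#'
#' Calls a sample tumor iff its vote fraction strictly exceeds `threshold`.
#' At the default cutoff 0.5 this reproduces the strict-majority voting rule
#' exactly.
#'
#' @param fractions numeric vote fractions named by sample id.
#' @param truth binary labels named by sample id.
#' @param threshold cutoff in \[0, 1\], default 0.5.
#' @return list with `sensitivity`, `specificity`, and the implied `calls`.
#' @export
threshold_metrics <- function(fractions, truth, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (!is.null(names(fractions)) && !is.null(names(truth)))
    truth <- truth[names(fractions)]
  is_tumor <- truth == "TUMOR"
  call_tumor <- fractions > threshold
  list(sensitivity = sum(call_tumor & is_tumor) / sum(is_tumor),
       specificity = sum(!call_tumor & !is_tumor) / sum(!is_tumor),
       calls = ifelse(call_tumor, "TUMOR", "NONTUMOR"))
}

#' Full evaluation of a signature on a labeled cohort
#'
#' Classifies the cohort by majority vote and assembles the complete
#' evaluation report: confusion metrics at the strict-majority rule plus
#' rank-sum AUC (with bootstrap CI) over the vote fractions.
#'
#' @param cohort a [labeled_cohort()] with both binary classes.
#' @param signature a [signature_model()].
#' @param n_bootstrap,seed bootstrap settings for the AUC interval.
#' @param max_missing forwarded to [classify_cohort()].
#' @return an `evaluation_report` with all fields filled.
#' @export
evaluate_signature <- function(cohort, signature, n_bootstrap = 2000L,
                               seed = 1L, max_missing = 0.25) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  calls <- classify_cohort(cohort$matrix, signature, max_missing)
  rep <- confusion_metrics(calls, cohort$binary)
  fr <- calls$fraction; names(fr) <- calls$sample_id
  roc <- roc_auc(fr, cohort$binary, n_bootstrap, seed)
  rep$auc <- roc$auc
  rep$auc_ci_low <- roc$ci_low
  rep$auc_ci_high <- roc$ci_high
  rep$n_bootstrap <- roc$n_bootstrap
  rep$seed <- roc$seed
  rep
}
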