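#' Construct a frozen gene-pair signature
#'
#' A signature is an ordered list of tumor-oriented gene pairs; a sample is
#' called tumor when strictly more than half of the pairs show their tumor
#' orientation.  Pairs may share genes (published panels often reuse a few
#' hub genes), but a gene never pairs with itself.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (tumor-oriented:
#'   a above b in tumors); a `score` column is carried along when present.
#' @param metric_trace optional numeric vector: the selection metric at each
#'   candidate panel size k (kept for provenance and plotting).
#' @param provenance free-text description of how the signature was trained
#'   (thresholds, cohorts, seed).
#' @return an object of class `signature_model` with elements `pairs`, `k`,
#'   `metric_trace`, `provenance`.
#' @export
signature_model <- function(pairs, metric_trace = NULL, provenance = "") {
  if (!is.data.frame(pairs) || !all(c("gene_a", "gene_b") %in% names(pairs)))
    stop("pairs must be a data.frame with gene_a and gene_b columns")
  if (!nrow(pairs)) stop("a signature must contain at least one gene pair")
  if (any(pairs$gene_a == pairs$gene_b))
    stop("a gene cannot be paired with itself: ",
         paste(pairs$gene_a[pairs$gene_a == pairs$gene_b], collapse = ", "))
  if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b)))
    stop("signature contains duplicated pairs")
  if (is.null(pairs$score)) pairs$score <- NA_real_
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs[, intersect(c("gene_a", "gene_b", "score"), names(pairs))],
         k = nrow(pairs),
         metric_trace = metric_trace,
         provenance = provenance),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d gene pairs, %d distinct genes\n",
              x$k, length(unique(c(x$pairs$gene_a, x$pairs$gene_b)))))
  print(x$pairs, row.names = TRUE)
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Majority-vote classification of every sample in a matrix
#'
#' Each signature pair casts a tumor vote in a sample when its tumor-oriented
#' REO indicator is 1 there (gene_a strictly above gene_b).  A sample is
#' called `TUMOR` iff strictly more than half of the evaluable pairs vote
#' tumor; at exactly half the call is `NONTUMOR` (the rule requires a strict
#' majority).  The vote depends only on the one sample's values.
#'
#' Pairs with a gene absent from the matrix are unevaluable; if their
#' fraction exceeds `max_missing` the classifier refuses to call (error),
#' otherwise the evaluable pairs vote and the total shrinks accordingly.
#'
#' @param matrix expression matrix of the samples to classify.
#' @param signature a [signature_model()].
#' @param max_missing maximum tolerated fraction of unevaluable pairs,
#'   default 0.25.
#' @return data.frame with one row per sample, order preserved: `sample_id`,
#'   `tumor_votes`, `total`, `fraction` (= tumor_votes / total), `call`.
#' @export
classify_cohort <- function(matrix, signature, max_missing = 0.25) {
  check_expression_matrix(matrix, "matrix")
  stopifnot(inherits(signature, "signature_model"))
  pr <- signature$pairs
  present <- pr$gene_a %in% rownames(matrix) & pr$gene_b %in% rownames(matrix)
  n_missing <- sum(!present)
  if (n_missing / nrow(pr) > max_missing)
    stop(sprintf(paste0("refusing to call: %d of %d signature pairs are ",
                        "unevaluable (missing genes: %s), above the allowed ",
                        "fraction %.2f"),
                 n_missing, nrow(pr),
                 paste(setdiff(unique(c(pr$gene_a, pr$gene_b)), rownames(matrix)),
                       collapse = ", "),
                 max_missing))
  pr <- pr[present, , drop = FALSE]
  votes <- colSums(matrix[pr$gene_a, , drop = FALSE] >
                   matrix[pr$gene_b, , drop = FALSE])
  total <- nrow(pr)
  data.frame(
    sample_id = colnames(matrix),
    tumor_votes = as.integer(votes),
    total = total,
    fraction = votes / total,
    call = ifelse(votes > total / 2, "TUMOR", "NONTUMOR"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Majority vote on a single sample
#'
#' @inheritParams classify_cohort
#' @param sample_id the sample to classify.
#' @return one-row data.frame as in [classify_cohort()].
#' @export
vote <- function(matrix, signature, sample_id, max_missing = 0.25) {
  check_expression_matrix(matrix, "matrix")
  if (length(sample_id) != 1L || !sample_id %in% colnames(matrix))
    stop("unknown sample_id: ", paste(sample_id, collapse = ", "))
  classify_cohort(matrix[, sample_id, drop = FALSE], signature, max_missing)
}

#' Forward selection of the minimal best gene-pair panel
#'
#' Walks down the score-sorted candidate list one pair at a time: for each
#' panel size k in 1..`k_max` the top-k pairs classify the training cohort by
#' majority vote and the panel is scored by the geometric mean of sensitivity
#' and specificity (or plain accuracy).  The returned signature is the panel
#' at the smallest k attaining the maximum metric — the minimal panel with
#' the best training performance.
#'
#' @param sorted_scores data.frame of candidates in descending score order
#'   (see [sort_by_score()]), tumor-oriented.
#' @param train a [labeled_cohort()] with both binary classes.
#' @param k_max largest panel size to consider; default all candidates,
#'   conventionally capped at the tuned-candidate count.
#' @param metric `"gmean"` (default) or `"accuracy"`.
#' @return a [signature_model()] whose `metric_trace` holds the per-k metric
#'   (length `k_max`) and whose `provenance` records the selection settings.
#' @export
forward_select <- function(sorted_scores, train, k_max = nrow(sorted_scores),
                           metric = c("gmean", "accuracy")) {
  metric <- match.arg(metric)
  stopifnot(inherits(train, "labeled_cohort"))
  if (!nrow(sorted_scores)) stop("no candidate pairs to select from")
  if (k_max < 1L || k_max > nrow(sorted_scores))
    stop("k_max must be between 1 and the number of candidates")
  if (!all(c("TUMOR", "NONTUMOR") %in% train$binary))
    stop("training cohort must contain both TUMOR and NONTUMOR samples")
  cand <- sorted_scores[seq_len(k_max), , drop = FALSE]
  m <- train$matrix
  missing <- setdiff(unique(c(cand$gene_a, cand$gene_b)), rownames(m))
  if (length(missing)) stop("gene not in training cohort: ", paste(missing, collapse = ", "))
  ind <- (m[cand$gene_a, , drop = FALSE] > m[cand$gene_b, , drop = FALSE]) * 1L
  cum_votes <- apply(ind, 2L, cumsum)                  # k x samples
  if (k_max == 1L) cum_votes <- matrix(cum_votes, nrow = 1L,
                                       dimnames = list(NULL, colnames(m)))
  truth_tumor <- train$binary == "TUMOR"
  trace <- vapply(seq_len(k_max), function(k) {
    call_tumor <- cum_votes[k, ] > k / 2
    tp <- sum(call_tumor & truth_tumor); fn <- sum(!call_tumor & truth_tumor)
    tn <- sum(!call_tumor & !truth_tumor); fp <- sum(call_tumor & !truth_tumor)
    if (metric == "gmean") sqrt(tp / (tp + fn) * tn / (tn + fp))
    else (tp + tn) / length(call_tumor)
  }, numeric(1))
  k_best <- which.max(trace)                            # smallest k at the max
  signature_model(
    cand[seq_len(k_best), , drop = FALSE],
    metric_trace = trace,
    provenance = sprintf(
      "forward selection over %d candidates on %d-sample training cohort; metric=%s; best %s=%.4f at k=%d",
      k_max, ncol(m), metric, metric, trace[k_best], k_best))
}
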