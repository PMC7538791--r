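#' Within-sample rank difference of a gene pair
#'
#' `R_ab = rank(a) - rank(b)` within one sample, with ranks taken over the
#' full gene universe (rank 1 = lowest).  Under the tumor-pattern
#' orientation, tumor samples are expected to show positive rank differences
#' and non-tumor samples negative ones.
#'
#' @param matrix expression matrix.
#' @param gene_a,gene_b gene identifiers.
#' @param sample_id sample identifier(s); `NULL` evaluates all samples.
#' @return numeric vector of rank differences, named by sample.
#' @export
rank_difference <- function(matrix, gene_a, gene_b, sample_id = NULL) {
  check_expression_matrix(matrix, "matrix")
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(matrix)) stop("gene not in matrix: ", g)
  if (is.null(sample_id)) sample_id <- colnames(matrix)
  missing <- setdiff(sample_id, colnames(matrix))
  if (length(missing)) stop("unknown sample_id: ", paste(missing, collapse = ", "))
  r <- rank_matrix(matrix[, sample_id, drop = FALSE])
  out <- r[gene_a, ] - r[gene_b, ]
  names(out) <- sample_id
  out
}

#' Zero out rank differences with the wrong sign
#'
#' Within one class the rank differences of a true reversal pair should all
#' share a sign (+ in tumor, - in non-tumor under the tumor-pattern
#' orientation).  Samples violating the expected sign would inflate the
#' class mean through the absolute value, so they are forced to zero before
#' averaging; conforming values and exact zeros pass through unchanged.
#'
#' @param values numeric vector of per-sample rank differences.
#' @param expected_sign `+1` (tumor class) or `-1` (non-tumor class).
#' @return the adjusted vector.
#' @export
zero_wrong_sign <- function(values, expected_sign) {
  if (!expected_sign %in% c(-1, 1)) stop("expected_sign must be +1 or -1")
  if (expected_sign > 0) pmax(values, 0) else pmin(values, 0)
}

#' Reversal scores of candidate gene pairs
#'
#' For each tumor-oriented pair, computes the mean wrong-sign-zeroed rank
#' difference in the tumor samples and in the non-tumor samples, and scores
#' the pair by the geometric mean of their magnitudes:
#' `score = sqrt(|mean_T| * |mean_N|)`.  A larger score indicates a stronger
#' and more consistent reversal of the pair's ordering between the classes.
#' Ranks are computed over the cohort's full gene universe.
#'
#' @param cohort a [labeled_cohort()] with both binary classes.
#' @param pairs data.frame of tumor-oriented pairs (`gene_a`, `gene_b`),
#'   e.g. the output of [reversal_pairs()] or [tuning_filter()].
#' @return `pairs` with columns `mean_tumor_rankdiff` (>= 0),
#'   `mean_nontumor_rankdiff` (<= 0) and `score` (>= 0) appended.
#' @export
score_reversal_pairs <- function(cohort, pairs) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (!all(c("TUMOR", "NONTUMOR") %in% cohort$binary))
    stop("cohort must contain both TUMOR and NONTUMOR samples")
  if (!nrow(pairs)) {
    pairs$mean_tumor_rankdiff <- numeric(0)
    pairs$mean_nontumor_rankdiff <- numeric(0)
    pairs$score <- numeric(0)
    return(pairs)
  }
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(cohort$matrix))
  if (length(missing)) stop("gene not in cohort: ", paste(missing, collapse = ", "))
  r <- rank_matrix(cohort$matrix)
  rd <- r[pairs$gene_a, , drop = FALSE] - r[pairs$gene_b, , drop = FALSE]
  tum <- cohort$binary == "TUMOR"
  mt <- rowMeans(pmax(rd[, tum, drop = FALSE], 0))
  mn <- rowMeans(pmin(rd[, !tum, drop = FALSE], 0))
  pairs$mean_tumor_rankdiff <- unname(mt)
  pairs$mean_nontumor_rankdiff <- unname(mn)
  pairs$score <- sqrt(abs(mt) * abs(mn))
  rownames(pairs) <- NULL
  pairs
}

#' Reversal score of a single pair
#'
#' Convenience wrapper around [score_reversal_pairs()] for one oriented
#' pair.
#'
#' @inheritParams score_reversal_pairs
#' @param gene_a,gene_b the tumor-oriented pair.
#' @return one-row data.frame with the score columns.
#' @export
reversal_score <- function(cohort, gene_a, gene_b) {
  score_reversal_pairs(cohort,
                       data.frame(gene_a = gene_a, gene_b = gene_b,
                                  stringsAsFactors = FALSE))
}

#' Sort scored pairs by descending reversal score
#'
#' Ties are broken lexicographically by (`gene_a`, `gene_b`) so that forward
#' selection is reproducible across runs and platforms.
#'
#' @param scored data.frame with a `score` column.
#' @return the data.frame in descending score order.
#' @export
sort_by_score <- function(scored) {
  if (!nrow(scored)) return(scored)
  ord <- order(-scored$score, scored$gene_a, scored$gene_b)
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
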