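#' FPKM to TPM conversion
#'
#' Rescales each sample so that its values sum to one million:
#' `TPM(g, s) = FPKM(g, s) / sum_g' FPKM(g', s) * 1e6`.  This is a positive
#' per-sample scaling, so it preserves every within-sample REO exactly; it is
#' applied only so that the absolute noise floor (TPM < 1) is meaningful.
#'
#' @param matrix expression matrix of FPKM values.
#' @return expression matrix of TPM values; every column sums to 1e6.
#' @export
fpkm_to_tpm <- function(matrix) {
  check_expression_matrix(matrix, "matrix")
  cs <- colSums(matrix)
  zero <- colnames(matrix)[cs == 0]
  if (length(zero))
    stop("cannot convert all-zero sample(s) to TPM: ", paste(zero, collapse = ", "))
  sweep(matrix, 2L, cs, "/") * 1e6
}

#' Remove genes below the expression noise floor
#'
#' A gene is considered noise and removed when its TPM is below `tpm_floor`
#' in strictly more than `sample_fraction` of the samples (default: < 1 TPM
#' in more than 90% of samples).  The boundary is strict: a gene low in
#' exactly 90% of samples is kept.
#'
#' @param matrix expression matrix (TPM scale).
#' @param tpm_floor positive expression floor.
#' @param sample_fraction fraction in (0, 1); genes low in more than this
#'   fraction of samples are dropped.
#' @return the filtered matrix; sample set unchanged, surviving gene order
#'   preserved.
#' @export
low_expression_filter <- function(matrix, tpm_floor = 1, sample_fraction = 0.90) {
  check_expression_matrix(matrix, "matrix")
  if (!(tpm_floor > 0)) stop("tpm_floor must be > 0")
  if (!(sample_fraction > 0 && sample_fraction < 1))
    stop("sample_fraction must be in (0, 1)")
  frac_low <- rowMeans(matrix < tpm_floor)
  keep <- frac_low <= sample_fraction          # removed iff strictly greater
  if (!any(keep))
    stop("low_expression_filter removed every gene; check the input scale")
  matrix[keep, , drop = FALSE]
}

#' Restrict several matrices to their common gene universe
#'
#' Pair mining across datasets from different platforms requires a shared
#' gene universe; this takes the intersection of the gene sets and returns
#' every matrix restricted to it, in one common gene order (the order of the
#' first matrix).
#'
#' @param matrices list of expression matrices.
#' @return list of matrices, all with the identical gene list in identical
#'   order.
#' @export
harmonize_gene_universe <- function(matrices) {
  if (!is.list(matrices) || !length(matrices))
    stop("matrices must be a non-empty list of expression matrices")
  for (m in matrices) check_expression_matrix(m, "matrices[[i]]")
  common <- rownames(matrices[[1L]])
  for (m in matrices[-1L]) common <- intersect(common, rownames(m))
  if (!length(common)) {
    counts <- vapply(matrices, nrow, integer(1))
    stop("gene universes have an empty intersection (per-matrix gene counts: ",
         paste(counts, collapse = ", "), ")")
  }
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Collapse duplicate gene rows by per-sample median
#'
#' Microarray platforms often carry several probes per gene symbol; before
#' REO analysis every symbol must map to a single row.  Duplicated rows are
#' collapsed to their per-sample median, a robust choice kept in this one
#' function so the policy is easy to change.
#'
#' @param values numeric matrix whose row names may contain duplicates.
#' @return matrix with unique row names, first-occurrence order.
#' @export
collapse_duplicate_genes <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("values must be a matrix with gene row names")
  if (!anyDuplicated(rownames(values))) return(values)
  genes <- unique(rownames(values))
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes) {
    rows <- which(rownames(values) == g)
    out[g, ] <- if (length(rows) == 1L) values[rows, ]
                else apply(values[rows, , drop = FALSE], 2L, stats::median)
  }
  out
}
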