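#' @details
#' The central object of the package is the within-sample relative expression
#' ordering (REO): for two genes a and b and one sample, the indicator of
#' whether a is expressed above b.  REOs are invariant to any strictly
#' monotone per-sample transformation of the expression scale, which is what
#' makes gene-pair signatures portable across platforms and batches without
#' normalization.
#'
#' @keywords internal
"_PACKAGE"

## Controlled vocabulary for clinical labels and their binary projection.
CLINICAL_LEVELS <- c("HEALTHY_NORMAL", "PANCREATITIS", "CANCER", "CANCER_ADJACENT")
TUMOR_LEVELS    <- c("CANCER", "CANCER_ADJACENT")
BINARY_LEVELS   <- c("NONTUMOR", "TUMOR")

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is an ordinary numeric matrix with unique gene
#' identifiers as row names and unique sample identifiers as column names.
#' Values must be finite and non-negative; missing values must be resolved
#' before entering the pipeline (REOs computed on imputed values are silently
#' wrong, so the core types simply refuse them).
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @param arg name used in error messages.
#' @return the validated matrix, invisibly unchanged.
#' @export
check_expression_matrix <- function(m, arg = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", arg))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("'%s' must have gene row names and sample column names", arg))
  if (anyDuplicated(rownames(m)))
    stop(sprintf("'%s' has duplicated gene identifiers: %s", arg,
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("'%s' has duplicated sample identifiers: %s", arg,
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  if (any(!is.finite(m)))
    stop(sprintf("'%s' contains non-finite values; resolve missing values before analysis", arg))
  if (any(m < 0))
    stop(sprintf("'%s' contains negative values; expression must be >= 0", arg))
  invisible(m)
}

#' Construct a labeled cohort
#'
#' Bundles an expression matrix with a four-level clinical label per sample
#' (`HEALTHY_NORMAL`, `PANCREATITIS`, `CANCER`, `CANCER_ADJACENT`) and its
#' binary tumor/non-tumor projection.  Cancer-adjacent normal tissue is
#' counted as tumor: its transcriptome resembles the tumor class, and the
#' signature is meant to flag it as such.  Healthy normal and pancreatitis
#' together form the non-tumor class.
#'
#' @param matrix expression matrix (see [check_expression_matrix()]).
#' @param clinical_labels character vector of clinical labels, either named
#'   by sample id or in column order of `matrix`.
#' @return an object of class `labeled_cohort`: a list with elements
#'   `matrix`, `clinical` (named character) and `binary` (named character,
#'   `TUMOR`/`NONTUMOR`).
#' @export
labeled_cohort <- function(matrix, clinical_labels) {
  check_expression_matrix(matrix, "matrix")
  samples <- colnames(matrix)
  lab <- as.character(clinical_labels)
  if (!is.null(names(clinical_labels))) {
    missing <- setdiff(samples, names(clinical_labels))
    if (length(missing))
      stop("no clinical label for sample(s): ", paste(missing, collapse = ", "))
    lab <- as.character(clinical_labels)[match(samples, names(clinical_labels))]
  } else if (length(lab) != length(samples)) {
    stop("clinical_labels must be named by sample id or match the number of samples")
  }
  bad <- setdiff(unique(lab), CLINICAL_LEVELS)
  if (length(bad))
    stop("unknown clinical label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CLINICAL_LEVELS, collapse = ", "), ")")
  names(lab) <- samples
  structure(
    list(matrix = matrix,
         clinical = lab,
         binary = binary_from_clinical(lab)),
    class = "labeled_cohort")
}

#' Binary tumor/non-tumor projection of clinical labels
#'
#' `CANCER` and `CANCER_ADJACENT` map to `TUMOR`; `HEALTHY_NORMAL` and
#' `PANCREATITIS` map to `NONTUMOR`.
#'
#' @param clinical character vector of clinical labels.
#' @return character vector of `TUMOR`/`NONTUMOR`, names preserved.
#' @export
binary_from_clinical <- function(clinical) {
  bad <- setdiff(unique(as.character(clinical)), CLINICAL_LEVELS)
  if (length(bad))
    stop("unknown clinical label(s): ", paste(bad, collapse = ", "))
  out <- ifelse(as.character(clinical) %in% TUMOR_LEVELS, "TUMOR", "NONTUMOR")
  names(out) <- names(clinical)
  out
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("labeled_cohort: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(clinical = x$clinical))
  print(table(binary = x$binary))
  invisible(x)
}

#' Within-sample expression ranks
#'
#' Ranks all genes of one sample by expression, with rank 1 the lowest
#' expressed gene and rank G the highest; tied values receive their average
#' rank, so the rank sum is always G(G+1)/2.
#'
#' @param matrix expression matrix.
#' @param sample_id one sample identifier.
#' @return named numeric vector of ranks over all genes.
#' @export
rank_within_sample <- function(matrix, sample_id) {
  check_expression_matrix(matrix, "matrix")
  if (length(sample_id) != 1L || !sample_id %in% colnames(matrix))
    stop("unknown sample_id: ", paste(sample_id, collapse = ", "))
  rank(matrix[, sample_id], ties.method = "average")
}

#' Rank matrix of a whole cohort
#'
#' Applies [rank_within_sample()] to every column.  Ranks are always taken
#' over the full gene universe of the matrix, never over a candidate subset.
#'
#' @param matrix expression matrix.
#' @return numeric matrix of the same shape containing within-sample ranks.
#' @export
rank_matrix <- function(matrix) {
  check_expression_matrix(matrix, "matrix")
  r <- apply(matrix, 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(matrix)
  r
}

#' REO indicator for an oriented gene pair
#'
#' Returns 1 where `gene_a` is expressed strictly above `gene_b` in a sample
#' and 0 otherwise.  Ties yield 0 for both orientations: a tie supports
#' neither ordering, so it is treated conservatively as "not above".
#'
#' @param matrix expression matrix.
#' @param gene_a,gene_b gene identifiers; orientation matters, `(a, b)`
#'   asserts "a above b".
#' @param sample_id sample identifier(s); `NULL` (default) evaluates all
#'   samples.
#' @return integer vector of 0/1, named by sample.
#' @export
reo_indicator <- function(matrix, gene_a, gene_b, sample_id = NULL) {
  check_expression_matrix(matrix, "matrix")
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(matrix)) stop("gene not in matrix: ", g)
  if (identical(gene_a, gene_b)) stop("a gene cannot be paired with itself: ", gene_a)
  if (is.null(sample_id)) sample_id <- colnames(matrix)
  missing <- setdiff(sample_id, colnames(matrix))
  if (length(missing)) stop("unknown sample_id: ", paste(missing, collapse = ", "))
  out <- as.integer(matrix[gene_a, sample_id] > matrix[gene_b, sample_id])
  names(out) <- sample_id
  out
}

#' Restrict a cohort to one binary class
#'
#' @param cohort a [labeled_cohort()].
#' @param class `"TUMOR"` or `"NONTUMOR"`.
#' @return expression matrix restricted to the samples of that class, sample
#'   order preserved, gene set unchanged.
#' @export
binary_projection <- function(cohort, class = c("TUMOR", "NONTUMOR")) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  class <- match.arg(class)
  keep <- names(cohort$binary)[cohort$binary == class]
  if (!length(keep))
    stop("cohort contains no ", class, " samples")
  cohort$matrix[, keep, drop = FALSE]
}

#' Restrict a cohort to one clinical label
#'
#' @param cohort a [labeled_cohort()].
#' @param label one of the four clinical labels.
#' @return expression matrix restricted to that label's samples.
#' @export
clinical_projection <- function(cohort, label) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  label <- match.arg(label, CLINICAL_LEVELS)
  keep <- names(cohort$clinical)[cohort$clinical == label]
  if (!length(keep))
    stop("cohort contains no ", label, " samples")
  cohort$matrix[, keep, drop = FALSE]
}

#' Subset a labeled cohort by sample ids
#'
#' @param cohort a [labeled_cohort()].
#' @param sample_ids sample identifiers to keep, in the given order.
#' @return a new `labeled_cohort`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  missing <- setdiff(sample_ids, colnames(cohort$matrix))
  if (length(missing)) stop("unknown sample_id: ", paste(missing, collapse = ", "))
  labeled_cohort(cohort$matrix[, sample_ids, drop = FALSE],
                 cohort$clinical[sample_ids])
}
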