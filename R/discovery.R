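## Pair mining works blockwise over the gene dimension so memory stays
## bounded at block_size x G counts even for large universes; results are
## identical to the naive double loop over all pairs (tested against it).

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Mine stable REO pairs of one sample group
#'
#' An oriented pair (a, b) is stable at fraction `threshold` when gene a is
#' expressed strictly above gene b in at least `threshold` of the group's
#' samples.  Thresholds must exceed 0.5 so that at most one orientation of
#' any unordered pair can qualify.
#'
#' @param matrix expression matrix of the sample group.
#' @param threshold stability fraction in (0.5, 1]; the default 0.85 is the
#'   conventional choice for cross-cohort REO signatures.
#' @param class_tag free-text tag recording which group produced the set.
#' @param block_size number of genes per mining block (memory/speed knob;
#'   does not affect results).
#' @return an object of class `stable_pairs`: list with `pairs` (data.frame
#'   `gene_a`, `gene_b`, `fraction`), `class_tag`, `threshold`, `n_samples`,
#'   `genes`.
#' @export
stable_pairs <- function(matrix, threshold = 0.85, class_tag = "unspecified",
                         block_size = 1024L) {
  check_expression_matrix(matrix, "matrix")
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must lie in (0.5, 1]: below 0.5 both orientations of a pair could qualify")
  if (ncol(matrix) < 2L) stop("stable-pair mining needs at least 2 samples")
  if (nrow(matrix) < 2L) stop("stable-pair mining needs at least 2 genes")
  G <- nrow(matrix); n <- ncol(matrix); genes <- rownames(matrix)
  res_a <- character(0); res_b <- character(0); res_f <- numeric(0)
  for (start in seq(1L, G, by = block_size)) {
    rows <- start:min(start + block_size - 1L, G)
    counts <- matrix(0L, length(rows), G)
    for (s in seq_len(n))
      counts <- counts + outer(matrix[rows, s], matrix[, s], ">")
    frac <- counts / n
    hit <- which(frac >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      keep <- rows[hit[, 1L]] != hit[, 2L]        # drop the self diagonal
      hit <- hit[keep, , drop = FALSE]
      res_a <- c(res_a, genes[rows[hit[, 1L]]])
      res_b <- c(res_b, genes[hit[, 2L]])
      res_f <- c(res_f, frac[hit])
    }
  }
  ord <- order(res_a, res_b)
  structure(
    list(pairs = data.frame(gene_a = res_a[ord], gene_b = res_b[ord],
                            fraction = res_f[ord], stringsAsFactors = FALSE),
         class_tag = class_tag, threshold = threshold,
         n_samples = n, genes = genes),
    class = "stable_pairs")
}

#' @export
print.stable_pairs <- function(x, ...) {
  cat(sprintf("stable_pairs [%s]: %d oriented pairs at threshold %.2f over %d samples (%d genes)\n",
              x$class_tag, nrow(x$pairs), x$threshold, x$n_samples, length(x$genes)))
  invisible(x)
}

#' Stable pairs of the non-tumor class across its two subgroups
#'
#' The non-tumor reference pattern must hold in healthy pancreas and in
#' pancreatitis alike, so an oriented pair qualifies only when it is stable
#' at `threshold` in each subgroup separately, with the same orientation
#' (the intersection of the two per-group stable sets).
#'
#' @param healthy,pancreatitis expression matrices of the two non-tumor
#'   subgroups, sharing one gene universe.
#' @param threshold stability fraction in (0.5, 1].
#' @return a `stable_pairs` object tagged `"NONTUMOR"`; `fraction` is the
#'   smaller of the two subgroup fractions, which both subgroups meet.
#' @export
stable_nontumor_pairs <- function(healthy, pancreatitis, threshold = 0.85) {
  check_expression_matrix(healthy, "healthy")
  check_expression_matrix(pancreatitis, "pancreatitis")
  if (!setequal(rownames(healthy), rownames(pancreatitis)))
    stop("healthy and pancreatitis matrices have different gene universes; ",
         "run harmonize_gene_universe() first")
  pancreatitis <- pancreatitis[rownames(healthy), , drop = FALSE]
  sh <- stable_pairs(healthy, threshold, class_tag = "HEALTHY_NORMAL")
  sp <- stable_pairs(pancreatitis, threshold, class_tag = "PANCREATITIS")
  kh <- pair_key(sh$pairs$gene_a, sh$pairs$gene_b)
  kp <- pair_key(sp$pairs$gene_a, sp$pairs$gene_b)
  idx <- match(kh, kp)
  keep <- !is.na(idx)
  pairs <- data.frame(
    gene_a = sh$pairs$gene_a[keep],
    gene_b = sh$pairs$gene_b[keep],
    fraction = pmin(sh$pairs$fraction[keep], sp$pairs$fraction[idx[keep]]),
    stringsAsFactors = FALSE)
  structure(
    list(pairs = pairs, class_tag = "NONTUMOR", threshold = threshold,
         n_samples = ncol(healthy) + ncol(pancreatitis),
         genes = rownames(healthy)),
    class = "stable_pairs")
}

#' Detect reversal gene pairs (RGPs)
#'
#' An RGP is an unordered gene pair whose stable orientation flips between
#' the classes: (a, b) stable in the tumor group and (b, a) stable in the
#' non-tumor group.  The result is oriented so that `gene_a` above `gene_b`
#' is the tumor pattern.
#'
#' @param tumor_stable,nontumor_stable `stable_pairs` objects built on a
#'   shared gene universe.
#' @return data.frame with columns `gene_a`, `gene_b`, `tumor_support`,
#'   `nontumor_support` (support fractions at which each class met its
#'   threshold), sorted by gene pair.
#' @export
reversal_pairs <- function(tumor_stable, nontumor_stable) {
  stopifnot(inherits(tumor_stable, "stable_pairs"),
            inherits(nontumor_stable, "stable_pairs"))
  if (!setequal(tumor_stable$genes, nontumor_stable$genes))
    stop("stable sets were built on different gene universes; ",
         "run harmonize_gene_universe() first")
  kt <- pair_key(tumor_stable$pairs$gene_a, tumor_stable$pairs$gene_b)
  kn_rev <- pair_key(nontumor_stable$pairs$gene_b, nontumor_stable$pairs$gene_a)
  idx <- match(kt, kn_rev)
  keep <- !is.na(idx)
  out <- data.frame(
    gene_a = tumor_stable$pairs$gene_a[keep],
    gene_b = tumor_stable$pairs$gene_b[keep],
    tumor_support = tumor_stable$pairs$fraction[keep],
    nontumor_support = nontumor_stable$pairs$fraction[idx[keep]],
    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Filter candidate RGPs on an independent tuning cohort
#'
#' Keeps an RGP only when the tumor tuning samples show the tumor pattern
#' and the non-tumor tuning samples show the reversed pattern, each in at
#' least `consistency` of the samples (default 1.0: unanimity, the strictest
#' reading of cross-dataset consistency).
#'
#' @param rgps data.frame of tumor-oriented RGPs (from [reversal_pairs()]).
#' @param tuning a [labeled_cohort()] containing both binary classes.
#' @param consistency required per-class agreement fraction, default 1.0.
#' @return the filtered data.frame with `tuning_tumor_support` and
#'   `tuning_nontumor_support` columns appended.
#' @export
tuning_filter <- function(rgps, tuning, consistency = 1.0) {
  stopifnot(inherits(tuning, "labeled_cohort"))
  if (!(consistency > 0 && consistency <= 1))
    stop("consistency must be in (0, 1]")
  if (!all(c("TUMOR", "NONTUMOR") %in% tuning$binary))
    stop("tuning cohort must contain both TUMOR and NONTUMOR samples")
  if (!nrow(rgps)) {
    rgps$tuning_tumor_support <- numeric(0)
    rgps$tuning_nontumor_support <- numeric(0)
    return(rgps)
  }
  m <- tuning$matrix
  missing <- setdiff(unique(c(rgps$gene_a, rgps$gene_b)), rownames(m))
  if (length(missing))
    stop("tuning cohort lacks RGP gene(s): ", paste(missing, collapse = ", "),
         "; harmonize gene universes before tuning")
  a <- m[rgps$gene_a, , drop = FALSE]
  b <- m[rgps$gene_b, , drop = FALSE]
  tum <- tuning$binary == "TUMOR"
  ft <- rowMeans((a > b)[, tum, drop = FALSE])
  fn <- rowMeans((b > a)[, !tum, drop = FALSE])
  keep <- ft >= consistency & fn >= consistency
  out <- rgps[keep, , drop = FALSE]
  out$tuning_tumor_support <- ft[keep]
  out$tuning_nontumor_support <- fn[keep]
  rownames(out) <- NULL
  out
}
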