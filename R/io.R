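SIGNATURE_FORMAT_VERSION <- "v1"

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects genes as rows: a header row of unique sample identifiers, a first
#' column of gene identifiers, and a tab-separated numeric body.  Any
#' non-numeric cell (including `NA`) is a parse error naming the cell —
#' missing values must be resolved upstream.  Duplicated gene rows are
#' collapsed to their per-sample median with a warning.
#'
#' @param path path to the TSV file.
#' @return a validated expression matrix.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (!nrow(raw) || ncol(raw) < 2L)
    stop("expression file is empty or has no sample columns: ", path)
  if (anyDuplicated(colnames(raw)[-1L]))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(colnames(raw)[-1L][duplicated(colnames(raw)[-1L])]), collapse = ", "))
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body),
                                    dimnames = list(genes, colnames(raw)[-1L])))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s' in %s",
                 body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 colnames(values)[bad[1L, 2L]], path))
  if (anyDuplicated(genes)) {
    warning("collapsing ", sum(duplicated(genes)),
            " duplicated gene row(s) by per-sample median in ", path)
    values <- collapse_duplicate_genes(values)
  }
  check_expression_matrix(values, basename(path))
  values
}

#' Write an expression matrix to TSV
#'
#' Genes as rows, samples as columns; values are echoed to 6 significant
#' digits (the package's stated round-trip precision).
#'
#' @param matrix expression matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  check_expression_matrix(matrix, "matrix")
  df <- data.frame(gene_id = rownames(matrix),
                   signif(matrix, 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical labels from TSV
#'
#' Two tab-separated columns: sample id and clinical label from the
#' controlled vocabulary (`HEALTHY_NORMAL`, `PANCREATITIS`, `CANCER`,
#' `CANCER_ADJACENT`).  A header line is detected by its first field being
#' `sample_id`.
#'
#' @param path path to the TSV file.
#' @return data.frame with `sample_id`, `clinical_label`, `binary_label`.
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) != 2L) stop("label file must have exactly two columns: ", path)
  if (identical(raw[1L, 1L], "sample_id")) raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) stop("label file is empty: ", path)
  ids <- raw[[1L]]; labels <- raw[[2L]]
  if (anyDuplicated(ids))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(unique(labels), CLINICAL_LEVELS)
  if (length(bad))
    stop("unknown clinical label(s) in ", path, ": ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CLINICAL_LEVELS, collapse = ", "), ")")
  names(labels) <- ids
  data.frame(sample_id = ids, clinical_label = unname(labels),
             binary_label = unname(binary_from_clinical(labels)),
             stringsAsFactors = FALSE)
}

#' Write per-sample clinical labels to TSV
#'
#' @param clinical named character vector of clinical labels (names are
#'   sample ids), e.g. the `clinical` element of a [labeled_cohort()].
#' @param path output path.
#' @export
write_labels_tsv <- function(clinical, path) {
  bad <- setdiff(unique(as.character(clinical)), CLINICAL_LEVELS)
  if (length(bad)) stop("unknown clinical label(s): ", paste(bad, collapse = ", "))
  utils::write.table(
    data.frame(sample_id = names(clinical), clinical_label = as.character(clinical)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a signature to a plain-text file
#'
#' The format is a versioned tab-separated dialect: comment-style header
#' lines carrying the format version, the panel size k, and free-text
#' provenance, followed by a column header and one row per oriented pair
#' (`gene_a` above `gene_b` in tumors) with its reversal score (6
#' significant digits; `NA` when not scored).
#'
#' @param signature a [signature_model()].
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "signature_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("#reosig_signature\t", SIGNATURE_FORMAT_VERSION),
    paste0("#k\t", signature$k),
    paste0("#provenance\t", gsub("[\r\n\t]+", " ", signature$provenance)),
    "gene_a\tgene_b\tscore"), con)
  writeLines(sprintf("%s\t%s\t%s", signature$pairs$gene_a, signature$pairs$gene_b,
                     ifelse(is.na(signature$pairs$score), "NA",
                            formatC(signature$pairs$score, digits = 6L, format = "g"))),
             con)
  invisible(path)
}

#' Read a signature file
#'
#' @param path path to a file written by [write_signature()] (or shipped
#'   with the package).
#' @return a [signature_model()].
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#reosig_signature"))
    stop("not a signature file (missing #reosig_signature header): ", path)
  version <- sub("^#reosig_signature\t", "", lines[1L])
  if (!identical(version, SIGNATURE_FORMAT_VERSION))
    stop("unsupported signature format version '", version, "' (expected ",
         SIGNATURE_FORMAT_VERSION, ")")
  header <- lines[startsWith(lines, "#")]
  prov_line <- header[startsWith(header, "#provenance")]
  provenance <- if (length(prov_line)) sub("^#provenance\t?", "", prov_line[1L]) else ""
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body) || !identical(body[1L], "gene_a\tgene_b\tscore"))
    stop("malformed signature file (missing column header): ", path)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != 3L))
    stop("malformed pair line in signature file: ",
         body[-1L][which(lengths(rows) != 3L)[1L]])
  pairs <- data.frame(
    gene_a = vapply(rows, `[[`, character(1), 1L),
    gene_b = vapply(rows, `[[`, character(1), 2L),
    score = suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L))),
    stringsAsFactors = FALSE)
  sig <- signature_model(pairs, provenance = provenance)
  k_line <- header[startsWith(header, "#k")]
  if (length(k_line)) {
    k <- as.integer(sub("^#k\t", "", k_line[1L]))
    if (!is.na(k) && k != sig$k)
      stop(sprintf("signature file declares k=%d but contains %d pairs: %s",
                   k, sig$k, path))
  }
  sig
}

#' The packaged 12-pair pancreatic-cancer signature
#'
#' Loads the published 12-gene-pair / 17-gene panel for discriminating
#' pancreatic tumor tissue (including cancer-adjacent normal) from benign
#' pancreas (healthy or pancreatitis).  Each pair is oriented with gene A
#' above gene B in tumors; the orientation rests on the recorded assumption
#' that the panel's recurring genes (LAMC2, S100P, CST6, CDH3) are the
#' tumor-overexpressed members, as noted in the file's provenance.
#'
#' @return a [signature_model()] with 12 pairs over 17 distinct genes.
#' @export
packaged_pc_signature <- function() {
  read_signature(system.file("extdata", "pc12_signature.tsv",
                             package = "reosig", mustWork = TRUE))
}
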