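## Independent brute-force oracles and small fixture builders.  The oracles
## deliberately use the slowest, most literal formulation of each definition
## so they stay independent of the package's optimized code paths.

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 1),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

## naive stable-pair mining: double loop over all unordered pairs
naive_stable_pairs <- function(m, threshold) {
  genes <- rownames(m)
  out_a <- character(0); out_b <- character(0); out_f <- numeric(0)
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i == j) next
    frac <- mean(m[i, ] > m[j, ])
    if (frac >= threshold) {
      out_a <- c(out_a, genes[i]); out_b <- c(out_b, genes[j])
      out_f <- c(out_f, frac)
    }
  }
  ord <- order(out_a, out_b)
  data.frame(gene_a = out_a[ord], gene_b = out_b[ord], fraction = out_f[ord],
             stringsAsFactors = FALSE)
}

## naive RGP detection straight from the definition, per unordered pair
naive_rgps <- function(tumor_m, healthy_m, panc_m, threshold) {
  genes <- rownames(tumor_m)
  out <- list()
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i == j) next
    a <- genes[i]; b <- genes[j]
    ft <- mean(tumor_m[a, ] > tumor_m[b, ])
    fh <- mean(healthy_m[b, ] > healthy_m[a, ])
    fp <- mean(panc_m[b, ] > panc_m[a, ])
    if (ft >= threshold && fh >= threshold && fp >= threshold)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, tumor_support = ft,
        nontumor_support = min(fh, fp), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      tumor_support = numeric(0), nontumor_support = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## AUC by exhaustive tumor x non-tumor comparison, ties counting one half
naive_auc <- function(scores, is_tumor) {
  t_sc <- scores[is_tumor]; n_sc <- scores[!is_tumor]
  tot <- 0
  for (x in t_sc) for (y in n_sc)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(t_sc) * length(n_sc))
}

pair_keys <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")

## small labeled cohort with planted reversal structure, for pipeline tests
small_sim <- function(seed, n_genes = 60L, n_planted = 8L,
                      penetrance = 0.95, sample_seed = NULL, ...) {
  cfg <- simulation_config(
    n_genes = n_genes, n_cancer = 14L, n_adjacent = 4L,
    n_healthy = 10L, n_pancreatitis = 10L,
    n_planted_pairs = n_planted,
    penetrance_tumor = penetrance, penetrance_nontumor = penetrance,
    seed = seed, sample_seed = sample_seed, ...)
  generate_cohort(cfg)
}

## run discovery -> scoring -> selection on a cohort; returns all artifacts
run_pipeline <- function(cohort, threshold = 0.85, k_max = 10L) {
  st <- stable_pairs(binary_projection(cohort, "TUMOR"), threshold, "TUMOR")
  sn <- stable_nontumor_pairs(clinical_projection(cohort, "HEALTHY_NORMAL"),
                              clinical_projection(cohort, "PANCREATITIS"),
                              threshold)
  rg <- reversal_pairs(st, sn)
  sc <- sort_by_score(score_reversal_pairs(cohort, rg))
  sig <- forward_select(sc, cohort, k_max = min(k_max, nrow(sc)))
  list(tumor_stable = st, nontumor_stable = sn, rgps = rg,
       scored = sc, signature = sig)
}
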