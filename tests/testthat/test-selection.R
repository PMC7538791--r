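## build a matrix + signature where sample columns realize a chosen number of
## tumor-pattern pairs out of k
vote_fixture <- function(k) {
  genes <- c(sprintf("A%02d", 1:k), sprintf("B%02d", 1:k))
  sig <- signature_model(data.frame(gene_a = sprintf("A%02d", 1:k),
                                    gene_b = sprintf("B%02d", 1:k),
                                    stringsAsFactors = FALSE))
  make_sample <- function(j) {   # first j pairs tumor-pattern (A > B)
    a <- ifelse(seq_len(k) <= j, 2, 1)
    b <- ifelse(seq_len(k) <= j, 1, 2)
    c(a, b)
  }
  m <- vapply(0:k, make_sample, numeric(2 * k))
  dimnames(m) <- list(genes, sprintf("v%02d", 0:k))
  list(matrix = m, signature = sig)
}

test_that("majority vote requires strictly more than half tumor-pattern pairs", {
  fx <- vote_fixture(12)
  res <- classify_cohort(fx$matrix, fx$signature)
  expect_equal(res$tumor_votes, 0:12)
  expect_equal(res$total, rep(12L, 13))
  expect_equal(res$fraction, (0:12) / 12)
  expect_equal(res$call, ifelse(0:12 > 6, "TUMOR", "NONTUMOR"))
  ## 7 of 12 -> TUMOR, 6 of 12 -> NONTUMOR, 0 of 12 -> fraction 0
  expect_equal(res$call[res$tumor_votes == 7], "TUMOR")
  expect_equal(res$call[res$tumor_votes == 6], "NONTUMOR")
  expect_equal(res$fraction[res$tumor_votes == 0], 0)
})

test_that("a sample's vote ignores every other sample in the matrix", {
  fx <- vote_fixture(5)
  full <- classify_cohort(fx$matrix, fx$signature)
  single <- vote(fx$matrix, fx$signature, "v03")
  expect_equal(single, full[full$sample_id == "v03", ], ignore_attr = TRUE)
  shuffled <- classify_cohort(fx$matrix[, rev(colnames(fx$matrix))], fx$signature)
  expect_equal(shuffled[rev(seq_len(nrow(shuffled))), ], full, ignore_attr = TRUE)
})

test_that("missing signature genes shrink the total or trigger refusal", {
  fx <- vote_fixture(4)
  ## drop one pair's genes: 1/4 = 25% missing, allowed at the default policy
  m <- fx$matrix[setdiff(rownames(fx$matrix), c("A04", "B04")), ]
  res <- classify_cohort(m, fx$signature)
  expect_equal(unique(res$total), 3L)
  ## drop two pairs: 50% missing, above the default 25% cap
  m2 <- fx$matrix[setdiff(rownames(fx$matrix), c("A03", "B03", "A04", "B04")), ]
  expect_error(classify_cohort(m2, fx$signature), "refusing to call")
  expect_silent(classify_cohort(m2, fx$signature, max_missing = 0.5))
})

test_that("signature construction rejects self-pairs and duplicates", {
  expect_error(signature_model(data.frame(gene_a = "x", gene_b = "x")), "itself")
  expect_error(signature_model(data.frame(gene_a = c("x", "x"),
                                          gene_b = c("y", "y"))), "duplicated")
  expect_error(signature_model(data.frame(gene_a = character(0),
                                          gene_b = character(0))), "at least one")
  sig <- signature_model(data.frame(gene_a = c("p", "p"), gene_b = c("q", "r")))
  expect_equal(sig$k, 2L)   # shared genes across pairs are allowed
})

test_that("forward selection returns the smallest panel attaining the best metric", {
  sim <- small_sim(seed = 31)
  res <- run_pipeline(sim$cohort, k_max = 6L)
  sig <- res$signature
  k_max <- min(6L, nrow(res$scored))
  expect_length(sig$metric_trace, k_max)
  expect_equal(max(sig$metric_trace), sig$metric_trace[sig$k])
  expect_true(sig$k == which.max(sig$metric_trace))
  ## brute force: each k evaluated independently must reproduce the trace
  brute <- vapply(seq_len(k_max), function(k) {
    s <- signature_model(res$scored[1:k, c("gene_a", "gene_b")])
    confusion_metrics(classify_cohort(sim$cohort$matrix, s), sim$cohort$binary)$gmean
  }, numeric(1))
  expect_equal(sig$metric_trace, brute)
})

test_that("a perfectly separating single candidate yields k = 1 with metric 1", {
  m <- rbind(a = c(9, 9, 1, 1), b = c(1, 1, 9, 9), n1 = c(5, 5, 5, 5))
  colnames(m) <- c("t1", "t2", "c1", "c2")
  co <- labeled_cohort(m, c("CANCER", "CANCER", "HEALTHY_NORMAL", "PANCREATITIS"))
  cand <- data.frame(gene_a = "a", gene_b = "b", score = 3, stringsAsFactors = FALSE)
  sig <- forward_select(cand, co, k_max = 1L)
  expect_equal(sig$k, 1L)
  expect_equal(sig$metric_trace, 1)
})

test_that("metric ties resolve to the smaller panel", {
  ## two candidates both perfect: k = 1 and k = 2 tie at metric 1
  m <- rbind(a = c(9, 1), b = c(1, 9), c = c(8, 2), d = c(2, 8))
  colnames(m) <- c("t1", "n1")
  co <- labeled_cohort(m, c("CANCER", "HEALTHY_NORMAL"))
  cand <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"),
                     score = c(2, 1), stringsAsFactors = FALSE)
  sig <- forward_select(cand, co, k_max = 2L)
  expect_equal(sig$metric_trace, c(1, 1))
  expect_equal(sig$k, 1L)
})

test_that("classification and the chosen panel are unchanged by monotone distortion", {
  sim <- small_sim(seed = 33)
  res <- run_pipeline(sim$cohort)
  dm <- apply_monotone_distortion(sim$cohort$matrix, seed = 99)
  res2 <- run_pipeline(labeled_cohort(dm, sim$cohort$clinical))
  expect_equal(res2$signature$pairs, res$signature$pairs)
  expect_equal(res2$signature$k, res$signature$k)
  expect_equal(classify_cohort(dm, res$signature),
               classify_cohort(sim$cohort$matrix, res$signature))
})

test_that("held-out classification is perfect at penetrance 1 and low noise", {
  sim <- small_sim(seed = 35, penetrance = 1, noise_sd = 0.1)
  res <- run_pipeline(sim$cohort)
  held <- generate_cohort(simulation_config(
    n_genes = 60L, n_cancer = 14L, n_adjacent = 4L, n_healthy = 10L,
    n_pancreatitis = 10L, n_planted_pairs = 8L,
    penetrance_tumor = 1, penetrance_nontumor = 1, noise_sd = 0.1,
    seed = 35, sample_seed = 777))
  calls <- classify_cohort(held$cohort$matrix, res$signature)
  expect_equal(calls$call, unname(held$cohort$binary[calls$sample_id]))
})
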