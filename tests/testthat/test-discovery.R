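test_that("stable pairs apply the inclusive threshold per orientation", {
  ## a > b in 5/5 samples; c > d in 4/5 (0.8 < 0.85)
  m <- rbind(a = c(9, 9, 9, 9, 9),
             b = c(1, 1, 1, 1, 1),
             c = c(5, 5, 5, 5, 1),
             d = c(2, 2, 2, 2, 3))
  colnames(m) <- sprintf("s%d", 1:5)
  st <- stable_pairs(m, 0.85)
  keys <- pair_keys(st$pairs)
  expect_true("a\rb" %in% keys)
  expect_false("c\rd" %in% keys)
  expect_false("d\rc" %in% keys)
  expect_equal(st$threshold, 0.85)
  expect_error(stable_pairs(m, 0.5), "0.5")
  expect_error(stable_pairs(m, 1.2), "0.5")
  expect_error(stable_pairs(m[, 1, drop = FALSE], 0.85), "2 samples")
})

test_that("optimized stable-pair mining equals the naive double loop", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- random_expression(sample(5:30, 1), sample(4:20, 1), seed + 100)
    thr <- sample(c(0.7, 0.85, 1.0), 1)
    got <- stable_pairs(m, thr, block_size = 7L)$pairs
    want <- naive_stable_pairs(m, thr)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("no stable set contains both orientations, and sets shrink as the threshold rises", {
  for (seed in 1:5) {
    m <- random_expression(15, 9, seed)
    s1 <- stable_pairs(m, 0.7)
    s2 <- stable_pairs(m, 0.9)
    k1 <- pair_keys(s1$pairs); k2 <- pair_keys(s2$pairs)
    rev1 <- paste(s1$pairs$gene_b, s1$pairs$gene_a, sep = "\r")
    expect_length(intersect(k1, rev1), 0)
    expect_true(all(k2 %in% k1))
  }
})

test_that("non-tumor stable pairs are the same-orientation intersection of the two subgroups", {
  ## one pair concordant across subgroups, one orientation-conflicted
  healthy <- rbind(a = c(9, 9, 9), b = c(1, 1, 1), c = c(5, 5, 5), d = c(2, 2, 2))
  panc    <- rbind(a = c(8, 8, 8), b = c(2, 2, 2), c = c(1, 1, 1), d = c(6, 6, 6))
  colnames(healthy) <- paste0("h", 1:3); colnames(panc) <- paste0("p", 1:3)
  sn <- stable_nontumor_pairs(healthy, panc, 0.85)
  keys <- pair_keys(sn$pairs)
  expect_true("a\rb" %in% keys)          # (a,b) stable in both
  expect_false("c\rd" %in% keys)         # (c,d) in healthy but (d,c) in pancreatitis
  expect_false("d\rc" %in% keys)
  expect_error(stable_nontumor_pairs(healthy, panc[1:3, ]), "harmonize")
})

test_that("non-tumor intersection matches the brute-force oracle on random subgroups", {
  for (seed in 1:4) {
    h <- random_expression(12, 7, seed)
    p <- random_expression(12, 9, seed + 50)
    got <- stable_nontumor_pairs(h, p, 0.8)$pairs[, c("gene_a", "gene_b")]
    sh <- naive_stable_pairs(h, 0.8); sp <- naive_stable_pairs(p, 0.8)
    want_keys <- intersect(pair_keys(sh), pair_keys(sp))
    expect_setequal(pair_keys(got), want_keys)
  }
})

test_that("reversal pairs require opposite stable orientations across classes", {
  tum <- rbind(a = c(9, 9, 9), b = c(1, 1, 1), c = c(7, 7, 7), d = c(2, 2, 2))
  nt  <- rbind(a = c(1, 1, 1), b = c(9, 9, 9), c = c(7, 7, 7), d = c(2, 2, 2))
  colnames(tum) <- paste0("t", 1:3); colnames(nt) <- paste0("n", 1:3)
  st <- stable_pairs(tum, 0.85, "TUMOR")
  sn <- stable_pairs(nt, 0.85, "NONTUMOR")
  rg <- reversal_pairs(st, sn)
  keys <- pair_keys(rg)
  expect_true("a\rb" %in% keys)      # flips between classes
  expect_false("c\rd" %in% keys)     # same orientation in both classes
  expect_true(all(rg$tumor_support >= 0.85 & rg$nontumor_support >= 0.85))
})

test_that("discovery recovers exactly the planted pairs at penetrance 1 and low noise", {
  sim <- small_sim(seed = 5, penetrance = 1, noise_sd = 0.1)
  res <- run_pipeline(sim$cohort)
  planted <- sim$truth$planted_pairs
  expect_true(all(pair_keys(planted) %in% pair_keys(res$rgps)))
  ## every discovery reverses in the generating population
  expect_true(all(true_reversal_status(res$rgps, sim$truth)))
})

test_that("full RGP detection equals the naive per-definition loop on a small cohort", {
  sim <- small_sim(seed = 9, n_genes = 20L, n_planted = 4L, penetrance = 0.9)
  co <- sim$cohort
  st <- stable_pairs(binary_projection(co, "TUMOR"), 0.85, "TUMOR")
  sn <- stable_nontumor_pairs(clinical_projection(co, "HEALTHY_NORMAL"),
                              clinical_projection(co, "PANCREATITIS"), 0.85)
  got <- reversal_pairs(st, sn)
  want <- naive_rgps(binary_projection(co, "TUMOR"),
                     clinical_projection(co, "HEALTHY_NORMAL"),
                     clinical_projection(co, "PANCREATITIS"), 0.85)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("tuning filter keeps only pairs consistent across all tuning samples", {
  tum <- rbind(a = c(9, 9), b = c(1, 1), c = c(7, 7), d = c(2, 2))
  nt  <- rbind(a = c(1, 1), b = c(9, 9), c = c(2, 8), d = c(6, 2))
  m <- cbind(tum, nt)
  colnames(m) <- c("t1", "t2", "n1", "n2")
  tuning <- labeled_cohort(m, c("CANCER", "CANCER", "HEALTHY_NORMAL", "PANCREATITIS"))
  rgps <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"),
                     tumor_support = 1, nontumor_support = 1,
                     stringsAsFactors = FALSE)
  kept <- tuning_filter(rgps, tuning)
  expect_equal(kept$gene_a, "a")       # (c,d) violated in sample n2
  expect_equal(kept$tuning_tumor_support, 1)
  expect_equal(kept$tuning_nontumor_support, 1)
  empty <- tuning_filter(rgps[0, ], tuning)
  expect_equal(nrow(empty), 0L)
  all_tum <- labeled_cohort(m[, c("t1", "t2")], c("CANCER", "CANCER"))
  expect_error(tuning_filter(rgps, all_tum), "both TUMOR and NONTUMOR")
})

test_that("discovered sets are identical after per-sample monotone distortion", {
  sim <- small_sim(seed = 13)
  m <- sim$cohort$matrix
  dm <- apply_monotone_distortion(m, seed = 77)
  co2 <- labeled_cohort(dm, sim$cohort$clinical)
  r1 <- run_pipeline(sim$cohort)
  r2 <- run_pipeline(co2)
  expect_equal(r1$rgps, r2$rgps)
  expect_equal(r1$tumor_stable$pairs, r2$tumor_stable$pairs)
})
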