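test_that("simulation configs validate their fields and report all violations", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(n_genes = 10, n_planted_pairs = 6),
               "n_planted_pairs")
  expect_error(simulation_config(penetrance_tumor = 0), "penetrance_tumor")
  expect_error(simulation_config(penetrance_nontumor = 1.1), "penetrance_nontumor")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(scale_range = c(0, 2)), "strictly positive")
  err <- tryCatch(simulation_config(noise_sd = -1, penetrance_tumor = 2),
                  error = conditionMessage)
  expect_match(err, "noise_sd"); expect_match(err, "penetrance_tumor")
})

test_that("generation is bit-for-bit reproducible from the seed", {
  cfg <- simulation_config(n_genes = 40, n_cancer = 6, n_adjacent = 2,
                           n_healthy = 5, n_pancreatitis = 5,
                           n_planted_pairs = 5, seed = 99)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort$matrix, s2$cohort$matrix)
  expect_identical(s1$truth, s2$truth)
})

test_that("the world is fixed by the seed while samples vary with sample_seed", {
  base <- list(n_genes = 40, n_cancer = 6, n_adjacent = 2, n_healthy = 5,
               n_pancreatitis = 5, n_planted_pairs = 5, seed = 99)
  s1 <- generate_cohort(do.call(simulation_config, c(base, sample_seed = 1)))
  s2 <- generate_cohort(do.call(simulation_config, c(base, sample_seed = 2)))
  expect_identical(s1$truth$planted_pairs, s2$truth$planted_pairs)
  expect_identical(s1$truth$mean_tumor, s2$truth$mean_tumor)
  expect_false(identical(s1$cohort$matrix, s2$cohort$matrix))
})

test_that("planted pairs are gene-disjoint by default and reuse hubs in hub mode", {
  s <- small_sim(seed = 3)
  g <- c(s$truth$planted_pairs$gene_a, s$truth$planted_pairs$gene_b)
  expect_equal(anyDuplicated(g), 0L)
  sh <- small_sim(seed = 3, hub_genes = TRUE)
  expect_lt(length(unique(sh$truth$planted_pairs$gene_a)),
            nrow(sh$truth$planted_pairs))
  ## hub-mode pairs still reverse between the class-mean structures
  expect_true(all(true_reversal_status(sh$truth$planted_pairs, sh$truth)))
})

test_that("at penetrance 1 every planted pair is discoverable at the 0.85 threshold", {
  sim <- small_sim(seed = 51, penetrance = 1, noise_sd = 0.05)
  res <- run_pipeline(sim$cohort)
  expect_true(all(pair_keys(sim$truth$planted_pairs) %in% pair_keys(res$rgps)))
})

test_that("at penetrance 0.5 planted pairs are essentially undiscoverable at 0.85", {
  sim <- small_sim(seed = 52, penetrance = 0.5)
  co <- sim$cohort
  st <- stable_pairs(binary_projection(co, "TUMOR"), 0.85, "TUMOR")
  sn <- stable_nontumor_pairs(clinical_projection(co, "HEALTHY_NORMAL"),
                              clinical_projection(co, "PANCREATITIS"), 0.85)
  rgps <- reversal_pairs(st, sn)
  recovered <- sum(pair_keys(sim$truth$planted_pairs) %in% pair_keys(rgps))
  expect_lte(recovered, 1L)   # binomial tail at n >= 10 per group is ~1e-3
})

test_that("monotone distortion is the identity at neutral parameters and always preserves REOs", {
  m <- random_expression(25, 8, 61)
  ident <- apply_monotone_distortion(m, scale_range = c(1, 1),
                                     power_range = c(1, 1),
                                     shift_range = c(0, 0), seed = 1)
  expect_equal(unname(ident), unname(m), ignore_attr = TRUE)
  dst <- apply_monotone_distortion(m, seed = 2)
  expect_equal(rank_matrix(dst), rank_matrix(m))
  pars <- attr(dst, "distortion_params")
  expect_equal(nrow(pars), ncol(m))
  expect_true(all(pars$scale > 0 & pars$power > 0 & pars$shift >= 0))
  expect_error(apply_monotone_distortion(m, scale_range = c(-1, 1)),
               "strictly positive")
  expect_error(apply_monotone_distortion(m, power_range = c(0, 1)),
               "strictly positive")
})

test_that("cohort splitting is stratified, exhaustive, disjoint and seed-stable", {
  sim <- small_sim(seed = 71, n_genes = 30, n_planted = 4)
  co <- sim$cohort
  sp <- split_cohort(co, c(train = 0.5, tuning = 0.25, validation = 0.25), seed = 4)
  ids <- unlist(lapply(sp, function(s) colnames(s$matrix)))
  expect_setequal(ids, colnames(co$matrix))
  expect_equal(length(ids), length(unique(ids)))
  ## stratification: per-label counts within one sample of exact proportion
  for (lab in unique(co$clinical)) {
    n_lab <- sum(co$clinical == lab)
    got <- vapply(sp, function(s) sum(s$clinical == lab), numeric(1))
    expect_true(all(abs(got - n_lab * c(0.5, 0.25, 0.25)) <= 1))
  }
  sp2 <- split_cohort(co, c(train = 0.5, tuning = 0.25, validation = 0.25), seed = 4)
  expect_identical(lapply(sp, `[[`, "matrix"), lapply(sp2, `[[`, "matrix"))
  all_in <- split_cohort(co, c(train = 1, tuning = 0, validation = 0), seed = 1)
  expect_length(all_in, 1L)
  expect_equal(ncol(all_in$train$matrix), ncol(co$matrix))
  expect_error(split_cohort(co, c(a = 0.6, b = 0.6), seed = 1), "sum to 1")
})

test_that("pseudo-datasets drop disjointly sampled gene subsets but keep a shared core", {
  m <- random_expression(50, 6, 81)
  ds <- make_pseudo_datasets(m, n_datasets = 3, drop_fraction = 0.1, seed = 9)
  expect_length(ds, 3L)
  for (d in ds) expect_equal(nrow(d), 45L)
  harm <- harmonize_gene_universe(ds)
  expect_gt(nrow(harm[[1]]), 30L)
  expect_identical(rownames(harm[[1]]), rownames(harm[[3]]))
})

test_that("the full pipeline gives identical outputs on distorted and undistorted cohorts", {
  sim <- small_sim(seed = 91)
  dm <- apply_monotone_distortion(sim$cohort$matrix, seed = 13)
  co2 <- labeled_cohort(dm, sim$cohort$clinical)
  r1 <- run_pipeline(sim$cohort)
  r2 <- run_pipeline(co2)
  expect_equal(r1$rgps, r2$rgps)
  expect_equal(r1$signature$k, r2$signature$k)
  c1 <- classify_cohort(sim$cohort$matrix, r1$signature)
  c2 <- classify_cohort(dm, r2$signature)
  expect_equal(c1, c2)
  f1 <- c1$fraction; names(f1) <- c1$sample_id
  f2 <- c2$fraction; names(f2) <- c2$sample_id
  expect_equal(roc_auc(f1, sim$cohort$binary, 50, seed = 1)$auc,
               roc_auc(f2, sim$cohort$binary, 50, seed = 1)$auc)
})
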