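#' Configuration of a synthetic REO cohort
#'
#' The generator emulates the statistical structure the pair-mining analysis
#' assumes: a background of genes whose within-sample order is concordant
#' across classes, plus a planted set of reversal pairs whose order flips
#' between tumor and non-tumor samples with configurable penetrance.
#' Expression is log-normal: each gene has a class-specific mean on the log
#' scale and independent Gaussian log-scale noise, so values are positive
#' and intensity-like.
#'
#' Defaults mirror a multi-dataset training design at desk scale: 2,000
#' genes; 60 cancer + 20 cancer-adjacent (the tumor class) and 40 healthy +
#' 40 pancreatitis (the non-tumor class); 50 planted pairs; penetrance 0.95
#' per class; log-noise SD 0.3.  Planted pairs separate their two genes'
#' class means by `separation_sd` noise SDs (default 3), so penetrance — not
#' noise — is the binding constraint on recovery.
#'
#' @param n_genes number of genes.
#' @param n_cancer,n_adjacent tumor-class sample counts (cancer and
#'   cancer-adjacent normal).
#' @param n_healthy,n_pancreatitis non-tumor-class sample counts.
#' @param n_planted_pairs number of planted reversal pairs; their genes are
#'   disjoint unless `hub_genes = TRUE`.
#' @param penetrance_tumor,penetrance_nontumor probability in (0, 1] that a
#'   sample of the class displays the planted pattern for a given pair.
#' @param noise_sd log-scale noise SD (>= 0).
#' @param separation_sd separation of a planted pair's class means, in units
#'   of `noise_sd` (>= 3 keeps noise-driven order flips rare).
#' @param baseline_meanlog,baseline_sdlog log-scale location and spread of
#'   gene baselines.
#' @param scale_range,power_range,shift_range per-sample monotone distortion
#'   families for [apply_monotone_distortion()]: value -> scale *
#'   value^power + shift.
#' @param hub_genes when `TRUE`, planted pairs reuse a smaller set of
#'   tumor-high hub genes (up to 4 pairs per hub), mimicking published
#'   panels that pair one driver gene against several partners.
#' @param seed integer seed; generation is fully reproducible from it.  The
#'   seed fixes the generative "world" (gene baselines, planted pairs and
#'   their class means), so two configs sharing `seed`, `n_genes` and the
#'   planting settings describe cohorts drawn from the same population.
#' @param sample_seed integer seed for the sample-level draws (noise and
#'   per-sample pattern obedience); defaults to `seed`.  Keep `seed` fixed
#'   and vary `sample_seed` to draw independent cohorts (training, tuning,
#'   validation) from one world.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_cancer = 60L, n_adjacent = 20L,
                              n_healthy = 40L, n_pancreatitis = 40L,
                              n_planted_pairs = 50L,
                              penetrance_tumor = 0.95,
                              penetrance_nontumor = 0.95,
                              noise_sd = 0.3,
                              separation_sd = 3,
                              baseline_meanlog = 3, baseline_sdlog = 1.5,
                              scale_range = c(0.2, 5),
                              power_range = c(0.5, 2),
                              shift_range = c(0, 5),
                              hub_genes = FALSE,
                              seed = 1L,
                              sample_seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cancer = as.integer(n_cancer), n_adjacent = as.integer(n_adjacent),
              n_healthy = as.integer(n_healthy),
              n_pancreatitis = as.integer(n_pancreatitis),
              n_planted_pairs = as.integer(n_planted_pairs),
              penetrance_tumor = penetrance_tumor,
              penetrance_nontumor = penetrance_nontumor,
              noise_sd = noise_sd, separation_sd = separation_sd,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              scale_range = scale_range, power_range = power_range,
              shift_range = shift_range,
              hub_genes = isTRUE(hub_genes), seed = as.integer(seed),
              sample_seed = as.integer(if (is.null(sample_seed)) seed else sample_seed))
  problems <- character(0)
  if (2L * cfg$n_planted_pairs > cfg$n_genes)
    problems <- c(problems, "2 * n_planted_pairs must not exceed n_genes")
  counts <- c(cfg$n_cancer, cfg$n_adjacent, cfg$n_healthy, cfg$n_pancreatitis,
              cfg$n_planted_pairs)
  if (any(counts < 0L)) problems <- c(problems, "all counts must be >= 0")
  for (p in c("penetrance_tumor", "penetrance_nontumor"))
    if (!(cfg[[p]] > 0 && cfg[[p]] <= 1))
      problems <- c(problems, paste(p, "must lie in (0, 1]"))
  if (cfg$noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (cfg$separation_sd < 0) problems <- c(problems, "separation_sd must be >= 0")
  for (r in c("scale_range", "power_range", "shift_range")) {
    v <- cfg[[r]]
    if (length(v) != 2L || v[1L] > v[2L])
      problems <- c(problems, paste(r, "must be an increasing pair"))
  }
  if (any(cfg$scale_range <= 0) || any(cfg$power_range <= 0))
    problems <- c(problems, "scale and power ranges must be strictly positive (monotonicity)")
  if (any(cfg$shift_range < 0)) problems <- c(problems, "shift_range must be >= 0")
  if (length(problems))
    stop("invalid simulation config:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "sim_config")
}

## Run code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a labeled synthetic cohort with planted reversal pairs
#'
#' Background genes share one log-scale baseline across classes, so their
#' relative order is concordant between tumor and non-tumor samples up to
#' noise.  Each planted pair (a, b) is tumor-oriented: the class means put a
#' above b by `separation_sd * noise_sd` in tumor samples and b above a in
#' non-tumor samples.  Each sample obeys its class's pattern independently
#' per pair with probability equal to the class penetrance; otherwise the
#' pair's two values are exchanged, flipping the order.  Cancer-adjacent
#' samples follow the tumor pattern.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (a [labeled_cohort()]) and `truth` (list with
#'   `planted_pairs`, a tumor-oriented data.frame; `clinical`, the label
#'   vector; and `mean_tumor` / `mean_nontumor`, the class-specific log-scale
#'   gene means defining the population ordering structure).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  npp <- config$n_planted_pairs
  d <- config$separation_sd * config$noise_sd / 2

  ## world: baselines, planted pairs and class means, fixed by config$seed
  world <- with_seed(config$seed, {
    if (config$hub_genes && npp > 0L) {
      n_hubs <- ceiling(npp / 4)
      picked <- sample(genes, n_hubs + npp)
      hubs <- picked[seq_len(n_hubs)]
      gene_a <- rep(hubs, length.out = npp)
      gene_b <- picked[n_hubs + seq_len(npp)]
    } else if (npp > 0L) {
      picked <- sample(genes, 2L * npp)
      gene_a <- picked[seq_len(npp)]
      gene_b <- picked[npp + seq_len(npp)]
    } else {
      gene_a <- gene_b <- character(0)
    }
    base <- stats::rnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    names(base) <- genes
    mean_tumor <- mean_nontumor <- base
    if (npp > 0L) {
      centre <- stats::rnorm(npp, config$baseline_meanlog, config$baseline_sdlog)
      if (config$hub_genes) {
        ## all pairs of one hub share the hub's centre so the hub's class
        ## means are single-valued and every partner still reverses with it
        hub_centre <- centre[match(unique(gene_a), gene_a)]
        centre <- hub_centre[match(gene_a, unique(gene_a))]
      }
      mean_tumor[gene_a] <- centre + d; mean_tumor[gene_b] <- centre - d
      mean_nontumor[gene_a] <- centre - d; mean_nontumor[gene_b] <- centre + d
    }
    list(gene_a = gene_a, gene_b = gene_b,
         mean_tumor = mean_tumor, mean_nontumor = mean_nontumor)
  })

  n_by_class <- c(CANCER = config$n_cancer, CANCER_ADJACENT = config$n_adjacent,
                  HEALTHY_NORMAL = config$n_healthy,
                  PANCREATITIS = config$n_pancreatitis)
  clinical <- rep(names(n_by_class), n_by_class)
  n <- length(clinical)
  if (n == 0L) stop("config yields zero samples")
  samples <- sprintf("S%04d", seq_len(n))
  names(clinical) <- samples
  is_tumor <- clinical %in% TUMOR_LEVELS

  ## samples: noise and per-sample pattern obedience, under sample_seed
  logx <- with_seed(config$sample_seed, {
    logx <- matrix(stats::rnorm(G * n, sd = config$noise_sd), G, n,
                   dimnames = list(genes, samples))
    logx <- logx + ifelse(rep(is_tumor, each = G),
                          world$mean_tumor, world$mean_nontumor)
    if (npp > 0L) {
      pen <- ifelse(is_tumor, config$penetrance_tumor, config$penetrance_nontumor)
      obey <- matrix(stats::runif(npp * n) <= rep(pen, each = npp), npp, n)
      for (p in seq_len(npp)) {
        flip <- which(!obey[p, ])
        if (!length(flip)) next
        a <- world$gene_a[p]; b <- world$gene_b[p]
        if (config$hub_genes) {
          ## reflect the partner across the hub so hub values stay shared
          logx[b, flip] <- 2 * logx[a, flip] - logx[b, flip]
        } else {
          tmp <- logx[a, flip]
          logx[a, flip] <- logx[b, flip]
          logx[b, flip] <- tmp
        }
      }
    }
    logx
  })

  cohort <- labeled_cohort(exp(logx), clinical)
  truth <- list(
    planted_pairs = data.frame(gene_a = world$gene_a, gene_b = world$gene_b,
                               stringsAsFactors = FALSE),
    clinical = clinical,
    mean_tumor = world$mean_tumor,
    mean_nontumor = world$mean_nontumor)
  list(cohort = cohort, truth = truth)
}

#' Judge discovered pairs against the generative population structure
#'
#' A discovered tumor-oriented pair (a, b) is a genuine reversal of the
#' generative model when the class-mean orderings reverse: a above b in the
#' tumor population and b above a in the non-tumor population.  Planted
#' genes are mean-shifted between classes, so they genuinely reverse not
#' only against their planted partner but also against background genes
#' whose baselines lie inside the shift window; such discoveries are true
#' reversals, not false positives.  A false positive is a discovered pair
#' whose population orderings do not reverse.
#'
#' @param pairs data.frame of tumor-oriented pairs (`gene_a`, `gene_b`).
#' @param truth the `truth` element returned by [generate_cohort()].
#' @return logical vector: `TRUE` where the pair reverses in the population.
#' @export
true_reversal_status <- function(pairs, truth) {
  stopifnot(all(c("mean_tumor", "mean_nontumor") %in% names(truth)))
  mt <- truth$mean_tumor; mn <- truth$mean_nontumor
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(mt))
  if (length(missing)) stop("gene absent from ground truth: ",
                            paste(missing, collapse = ", "))
  unname(mt[pairs$gene_a] > mt[pairs$gene_b] &
         mn[pairs$gene_b] > mn[pairs$gene_a])
}

#' Apply a per-sample strictly monotone distortion
#'
#' Emulates platform, batch, and scale effects: each sample's values are
#' transformed by `value -> scale * value^power + shift` with per-sample
#' parameters drawn uniformly from the given ranges.  The map is strictly
#' increasing on non-negative values, so every within-sample ordering — and
#' therefore every REO-based result — is preserved exactly.
#'
#' @param matrix expression matrix.
#' @param scale_range,power_range,shift_range parameter ranges; scale and
#'   power must be strictly positive.
#' @param seed integer seed for the per-sample draws.
#' @return the distorted matrix; the drawn parameters are attached as
#'   attribute `"distortion_params"` (data.frame per sample).
#' @export
apply_monotone_distortion <- function(matrix,
                                      scale_range = c(0.2, 5),
                                      power_range = c(0.5, 2),
                                      shift_range = c(0, 5),
                                      seed = 1L) {
  check_expression_matrix(matrix, "matrix")
  if (any(scale_range <= 0)) stop("scale must be strictly positive (monotonicity)")
  if (any(power_range <= 0)) stop("power must be strictly positive (monotonicity)")
  if (any(shift_range < 0)) stop("shift must be >= 0")
  n <- ncol(matrix)
  with_seed(seed, {
    pars <- data.frame(
      sample_id = colnames(matrix),
      scale = stats::runif(n, scale_range[1L], scale_range[2L]),
      power = stats::runif(n, power_range[1L], power_range[2L]),
      shift = stats::runif(n, shift_range[1L], shift_range[2L]),
      stringsAsFactors = FALSE)
    out <- matrix
    for (j in seq_len(n))
      out[, j] <- pars$scale[j] * matrix[, j]^pars$power[j] + pars$shift[j]
    attr(out, "distortion_params") <- pars
    out
  })
}

#' Stratified train / tuning / validation split
#'
#' Splits a cohort into disjoint, exhaustive subsets, stratified by clinical
#' label so each split keeps the cohort's class composition (within one
#' sample of exact proportionality per stratum).  Reproducible from `seed`.
#'
#' @param cohort a [labeled_cohort()].
#' @param fractions named numeric vector summing to 1, e.g.
#'   `c(train = 0.6, tuning = 0.1, validation = 0.3)`; zero fractions yield
#'   no cohort for that split.
#' @param seed integer seed.
#' @return named list of `labeled_cohort`s, one per non-empty split.
#' @export
split_cohort <- function(cohort,
                         fractions = c(train = 0.6, tuning = 0.1, validation = 0.3),
                         seed = 1L) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions))) stop("fractions must be named")
  assign_split <- with_seed(seed, {
    out <- character(ncol(cohort$matrix))
    names(out) <- colnames(cohort$matrix)
    for (lab in unique(cohort$clinical)) {
      ids <- sample(names(cohort$clinical)[cohort$clinical == lab])
      ## largest-remainder apportionment of this stratum over the splits
      quota <- fractions * length(ids)
      counts <- floor(quota)
      rem <- length(ids) - sum(counts)
      if (rem > 0) {
        extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      bounds <- cumsum(counts)
      start <- c(0, utils::head(bounds, -1)) + 1
      for (k in seq_along(fractions))
        if (counts[k] > 0)
          out[ids[start[k]:bounds[k]]] <- names(fractions)[k]
    }
    out
  })
  splits <- lapply(names(fractions)[fractions > 0], function(nm) {
    ids <- colnames(cohort$matrix)[assign_split[colnames(cohort$matrix)] == nm]
    if (!length(ids)) stop("split '", nm, "' received no samples")
    sub <- subset_cohort(cohort, ids)
    if (length(unique(sub$binary)) < 2L)
      stop("split '", nm, "' lost a binary class; use larger fractions or cohorts")
    sub
  })
  names(splits) <- names(fractions)[fractions > 0]
  splits
}

#' Derive pseudo-datasets with partially overlapping gene universes
#'
#' Mimics multi-platform cohorts by dropping a random fraction of genes from
#' each copy of the matrix, so [harmonize_gene_universe()] has realistic
#' input.
#'
#' @param matrix expression matrix.
#' @param n_datasets number of pseudo-datasets.
#' @param drop_fraction fraction of genes dropped from each copy (default
#'   0.10).
#' @param seed integer seed.
#' @return list of matrices with overlapping but distinct gene sets.
#' @export
make_pseudo_datasets <- function(matrix, n_datasets = 3L, drop_fraction = 0.10,
                                 seed = 1L) {
  check_expression_matrix(matrix, "matrix")
  if (!(drop_fraction >= 0 && drop_fraction < 1))
    stop("drop_fraction must be in [0, 1)")
  with_seed(seed, {
    lapply(seq_len(n_datasets), function(i) {
      drop <- sample(rownames(matrix), round(drop_fraction * nrow(matrix)))
      matrix[setdiff(rownames(matrix), drop), , drop = FALSE]
    })
  })
}
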