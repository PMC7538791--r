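---
title: "Qualitative gene-pair signatures from relative expression orderings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative gene-pair signatures from relative expression orderings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The problem and the model

Quantitative transcriptional classifiers are fragile in exactly the settings
where a molecular diagnosis is most needed: biopsy material measured on
heterogeneous platforms, with batch effects, variable tumor-cell fractions,
RNA degradation and amplification bias. `reosig` implements a *qualitative*
alternative built entirely on within-sample relative expression orderings
(REOs): for two genes $a$ and $b$ and a sample $s$, the only datum used is
the indicator

$$ I_{ab}(s) = \mathbf{1}\{x_a(s) > x_b(s)\}. $$

Because $I_{ab}$ depends only on the *order* of two measurements taken in
the same sample, it is exactly invariant under any strictly increasing
transformation applied to that sample's values — which is how normalization
differences, scanner scales and monotone batch distortions act to first
order. A signature assembled from such indicators can therefore be applied
to one sample at a time, with no normalization against a reference cohort.

The intended application is the pancreatic-cancer setting shipped with the
package: discriminating tumor tissue (cancer and cancer-adjacent normal,
whose transcriptome already resembles the tumor class) from benign pancreas
(healthy normal and pancreatitis). The four-level clinical vocabulary and
its fixed binary projection are part of the package's types.

## The discovery pipeline

1. **Stable pairs per class.** An oriented pair $(a, b)$ is *stable* in a
   sample group when $I_{ab} = 1$ in at least a fraction $f$ of the group's
   samples (default $f = 0.85$). The threshold is inclusive
   ($\geq f$) and must exceed $0.5$, which guarantees at most one
   orientation of a pair can qualify. For the non-tumor class, stability is
   required in the healthy and pancreatitis subgroups *separately*, with
   the same orientation — the reference pattern must hold across benign
   physiology, not merely on average.
2. **Reversal gene pairs (RGPs).** An RGP is a pair stable as $(a, b)$ in
   tumors and as $(b, a)$ in non-tumors. RGPs are recorded tumor-oriented.
3. **Tuning filter.** Candidates must reproduce both patterns in an
   independent tuning cohort; the default consistency level is 1.0
   (unanimity), read as the strictest form of cross-dataset consistency,
   and is exposed as a parameter.
4. **Reversal score.** Within each sample the rank difference
   $R_{ab} = R_a - R_b$ is taken over the full gene universe (rank 1 =
   lowest; ties get average ranks). Samples whose $R_{ab}$ has the
   wrong sign for their class are set to zero before averaging, because
   they would otherwise inflate the class mean through the absolute value.
   The score is the geometric mean of the magnitudes of the two class
   means, $\bar R_{ab} = \sqrt{|\bar R^T_{ab}| \cdot |\bar R^N_{ab}|}$;
   larger means a stronger, more consistent reversal.
5. **Forward selection.** Candidates are sorted by descending score (ties
   broken lexicographically so runs are reproducible) and added one at a
   time; each panel size $k$ is evaluated on the training cohort by the
   strict-majority vote, and the smallest $k$ attaining the maximum
   geometric mean of sensitivity and specificity is kept. The geometric
   mean is the default selection metric because it is the balanced summary
   appropriate to unequal class sizes; plain accuracy is available as an
   option.
6. **Majority-vote classification.** A sample is called tumor iff strictly
   more than half of the panel's pairs show their tumor orientation. At
   exactly half the call is non-tumor; this boundary is unit-tested for
   even panel sizes.

### Numerical conventions

* **Ties in expression** yield indicator 0 for both orientations and rank
  difference 0. A tie supports neither ordering, so this is the
  conservative choice; real intensity data essentially never ties, but
  rounded or quantized inputs can.
* **Rank direction**: rank 1 is the lowest expression, so "gene $a$ above
  gene $b$" corresponds to $R_{ab} > 0$, keeping the sign conventions of
  scoring and voting coherent.
* **Missing values are unrepresentable** in the core matrix type. REOs
  computed against imputed values would be silently wrong, so resolution
  (dropping genes or external imputation) must happen at load time.
* **Missing signature genes at application time**: pairs with an absent
  gene are unevaluable; if more than 25% of the panel is unevaluable the
  classifier refuses to call rather than degrade quietly, otherwise the
  evaluable pairs vote with a shrunken total. Both the policy and the
  threshold are parameters.
* **Mining scale**: stable-pair mining is blocked over the gene dimension
  (counts of size `block_size` × G), so memory stays bounded while results
  remain bit-identical to the naive double loop over all pairs, which is
  asserted in the test suite. A 2,000-gene, 200-sample class takes well
  under a minute on one CPU; genome-wide universes are a workstation batch
  job by design.

## Preprocessing

Two computations precede mining for RNA-seq inputs: FPKM→TPM conversion
(a per-sample positive scaling — it changes no REO and exists only so the
absolute noise floor is meaningful) and the noise filter that removes genes
with TPM < 1 in strictly more than 90% of samples. The strict boundary
means a gene low in exactly 90% of samples is kept. Cross-platform analyses
first intersect gene universes (`harmonize_gene_universe()`); the package
takes the intersection because mining requires every pair to be observable
in every pooled sample. Duplicate probe rows collapse to the per-sample
median — a robust choice isolated in one function.

Stability fractions are computed over the pooled samples of the merged
per-class training matrices (after harmonization), not per dataset with a
voting rule; pooling matches the single per-class counts the discovery
design reports.

## The synthetic-cohort generator

`generate_cohort()` produces labeled cohorts with exactly the structure the
pipeline assumes, so every stage can be tested against ground truth without
any external accession:

* **Background**: every gene has one log-scale baseline
  ($\mathcal{N}(3, 1.5^2)$) shared by both classes, plus independent
  Gaussian log-noise (SD 0.3) — a concordant REO background on positive,
  intensity-like values.
* **Planted pairs**: 50 gene-disjoint pairs by default. A pair's two genes
  sit symmetrically around a common centre, separated by
  `separation_sd` × `noise_sd` (default 3 noise SDs, so noise-driven order
  flips occur in only ~1.7% of obeying samples and penetrance is the
  binding constraint on discovery). Tumor samples put gene A on top;
  non-tumor samples reverse the separation. Each sample obeys its class
  pattern independently per pair with probability equal to the class
  penetrance (default 0.95); disobeying samples have the pair's two values
  exchanged. Cancer-adjacent samples follow the tumor pattern, matching
  the binary class definition.
* **Two-level seeding**: the `seed` fixes the generative *world*
  (baselines, planted pairs, class means); `sample_seed` drives the
  sample-level draws. Training, tuning and validation cohorts drawn with a
  shared `seed` therefore come from one population, which is what a
  train/tune/validate design requires.
* **Distortions**: `apply_monotone_distortion()` transforms each sample by
  $x \mapsto s\,x^{p} + c$ with per-sample $s \in [0.2, 5]$,
  $p \in [0.5, 2]$, $c \in [0, 5]$ — strictly increasing on non-negative
  values, standing in for platform/batch/scale effects. The pipeline's
  outputs must be bit-identical under it, and the test suite asserts this
  end to end.
* **Hub mode** (`hub_genes = TRUE`) reuses a tumor-high gene across up to
  four pairs (published panels do this), sharing one centre per hub;
  disobedience then reflects the partner across the hub's value so the
  hub's own values stay consistent across its pairs.

### What counts as a false discovery

A planted gene's class mean shifts between classes, so it genuinely
reverses not only against its planted partner but also against any
background gene whose baseline falls inside the shift window — at default
density that is hundreds of additional, *real* reversals of the generating
population. Calling those "false positives" would misread the simulation:
they are exactly what a correct miner should find. The ground truth
therefore records the class-mean vectors, and `true_reversal_status()`
judges each discovery against the population ordering structure: a false
positive is a discovered pair whose class-mean orderings do *not* reverse.
Planted-pair *recovery* is still counted against the exact planted list.
In the default study the pipeline recovers ≥ 90% of planted pairs with
zero population-false discoveries.

### What the generator does not emulate

Correlated co-expression modules, tumor purity gradients, count-level
(Poisson/negative-binomial) noise, platform-specific probe effects beyond
monotone maps, and non-monotone batch artifacts. Passing tests therefore
demonstrate correctness of the algorithms under the model's assumptions —
including exact rank invariance — not clinical performance on real tissue.

## Study sizes used in the packaged analyses

The numbered scripts under `analysis/` and the acceptance script run the
default design: a 160-sample training cohort (60 cancer, 20
cancer-adjacent, 40 healthy, 40 pancreatitis) over 2,000 genes with 50
planted pairs; a 6 + 6 tuning cohort; a 200-sample held-out cohort; forward
selection over the top 20 tuned candidates. These sizes mirror, at
workstation scale, a multi-dataset training design of a few hundred
samples, and keep a full run within a minute or two on one CPU.

## Evaluation

Sensitivity, specificity, accuracy and their geometric mean come from the
confusion table at the strict-majority rule (equivalently, the vote-fraction
cutoff 0.5 — "median of the voting range" is read as 0.5 and exposed as a
parameter). The AUC over vote fractions uses the rank-sum (Mann–Whitney)
formulation with ties counted one half, which equals the trapezoidal area
under the empirical ROC curve; the test suite asserts that equality against
an independent ROC implementation. The confidence interval is a stratified
percentile bootstrap (default 2,000 replicates) under a recorded seed —
chosen over closed-form variance approximations because it is
distribution-free, honest at the extreme AUCs this classifier reaches, and
exactly reproducible.

## The packaged signature

`packaged_pc_signature()` loads the published 12-pair, 17-gene
pancreatic-cancer panel shipped under `inst/extdata/`. Pairs are oriented
with gene A above gene B in tumors. The orientation rests on a recorded
assumption, stated in the file's provenance line: the panel's recurring
genes (LAMC2, S100P, CST6, CDH3) are the tumor-overexpressed members, in
line with their documented tumor biology. The signature file format is a
versioned plain-text dialect with provenance, panel size and per-pair
scores; round-trips preserve pairs exactly and scores to six significant
digits.

## Known limitations

* Discovery needs moderately large per-class sample counts: at $f = 0.85$
  a 20-sample group tolerates only three discordant samples, so sampling
  noise dominates below roughly that size.
* The tuning filter's unanimity default is aggressive for large tuning
  cohorts; lower the consistency level as the tuning set grows.
* Vote fractions are not calibrated probabilities; they order samples well
  (hence the AUC) but should not be read as risk.
* All guarantees are within-sample: any preprocessing that mixes values
  *across* samples non-monotonically (quantile normalization against a
  changing reference, for example) can alter REOs and is the user's
  responsibility to avoid.
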