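---
title: "Methods: storage-induced multi-omics shifts in fermentation microbiomes"
author: "sourstore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: storage-induced multi-omics shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sourstore` analyses how storage temperature and time restructure a
fermented-food (sourdough-type) microbiome and its metabolome. This vignette
is the package's account of the models it implements, the conventions it
fixes where the underlying methods leave freedom, and what its synthetic
benchmark can and cannot show.

## The experimental design being modelled

All defaults target a storage experiment of the following shape: sourdough
aliquots held at three constant temperatures (4, 17 and 30 °C), sampled at
11 time points over 28 days (daily for the first week, then days 10, 14, 21
and 28), in triplicate — 99 samples. Each sample carries a bacterial 16S
count table (a ~5-taxon lactic-acid-bacteria community), a fungal ITS count
table (a near-monoculture), an untargeted flow-injection MS metabolite
table (~150 features), and physicochemical covariates (pH, TTA, CFU, HPLC
sugars and acids, DNA concentration). Storage days are binned into phases:
phase 1 = days 1–4, phase 2 = days 5–10, phase 3 = day 14 onwards. The
phase-3 lower bound is exposed (`phase3_from`) because sampled days jump
from 10 to 14; we default to 14–28 so that every sampled day is covered.

## Compositional transforms

Sequencing counts and FIA-MS intensities are compositional: only relative
information is meaningful. The package therefore works through the standard
log-ratio pipeline:

* **TSS** (`tss_normalize()`): per-sample division by the total.
* **Multiplicative zero replacement** (`multiplicative_replacement()`,
  `delta = 1e-8`): zeros become `delta`, non-zero parts are rescaled so the
  sample still sums to 1. The small default follows common practice for
  detection-limit zeros; note it makes absent features extremely negative
  after the log-ratio step (|CLR| ≈ 13 and beyond), which matters for
  network scores (below).
* **CLR** (`clr_transform()`): `log(x / geometric mean(x))` per sample;
  sums to zero per sample, scale-invariant.
* **Z-scoring** (`zscore_normalize()`) standardises features across
  samples using the **population** (ddof = 0) standard deviation. The
  choice is arbitrary but must be fixed; population sd matches the default
  of the scipy/scikit-learn stack, so results are comparable with pipelines
  built there. Constant features are dropped with a message rather than
  producing NaNs.
* **Rarefaction** (`rarefy()`): multivariate-hypergeometric subsampling
  without replacement, one draw per sample, seeded; samples under the
  target depth are dropped and listed in the `"dropped"` attribute.
  Defaults elsewhere in the package mirror typical depths for this design
  (380 reads for 16S, 3500 for ITS).
* **Absolute scaling** (`absolute_abundance()`): qPCR-derived DNA
  concentrations are converted to cell-equivalents assuming 5 marker
  copies per cell and 1.58e9 copies per ng of DNA, then distributed over
  taxa by relative abundance. Column totals are conserved exactly.

## Diversity, ordination and permutation inference

Alpha diversity offers richness, Shannon entropy (natural log) and Pielou
evenness (undefined — `NA`, not 0 — when richness ≤ 1). Beta diversity
wraps Bray–Curtis and presence/absence Jaccard; a pair of all-zero samples
has no defined dissimilarity and is set to 0 with a warning.

**PCoA** eigendecomposes the Gower-centred matrix. Semimetric
dissimilarities produce negative eigenvalues; retained axes are those with
positive eigenvalues and explained proportions are computed over the
positive part only. The full spectrum is kept in the result because the
dispersion test needs it.

**PERMANOVA** (`permanova()`) partitions the squared dissimilarities into
among/within-group sums and permutes group labels;
`p = (#{F* ≥ F} + 1) / (n_perm + 1)`. The default of 999 permutations gives
the conventional p = 0.001 floor. The implementation is cross-checked in
the test suite against `vegan::adonis2` to 1e-10.

**PERMDISP** (`permdisp()`) computes each sample's distance to its group
centroid in principal-coordinate space, handling imaginary axes by
subtracting the squared imaginary-part distances (distances match
`vegan::betadisper(type = "centroid")` to 1e-10 in the tests). The F
statistic's null distribution is obtained by permuting the distances among
groups — the least-squares residual permutation, as in
`vegan::permutest.betadisper`. The per-group mean distances are first-class
output, since dispersion magnitudes are the scientific readout.

**Nested PERMANOVA** (`nested_permanova()`) is the package's two-level
design test: a global test of the primary factor, then a secondary-factor
PERMANOVA inside each primary level, with Benjamini–Hochberg correction
across the within-stratum family of one call. Each stratum reuses the
caller's seed, so a stratum row is bit-identical to manually subsetting
the distance matrix and calling `permanova()` — the property the test
suite asserts exactly. We report pseudo-F and R² separately and never
conflate them; R² is a variance fraction and cannot exceed 1.

## Co-occurrence and conditional-dependence networks

The abundance-weighted co-occurrence score of two CLR vectors is

    S(x, y) = sum(x_i * y_i * w_i) / sum(w_i),   w_i = |x_i * y_i|

a weighted average of signed products that upweights strong co-variation.
Two properties matter in practice. First, S is **unbounded** (a single
dominant product carries it: S([2,0],[3,5]) = 6), so the conventional edge
cut |S| ≥ 0.2 is a parameter (`threshold`), and a rank-based alternative
(`top_q`, keep the top fraction of |S|) is provided for robustness; the
default stays 0.2 for comparability. Second, because zero-replacement makes
absent features hugely negative in CLR, networks over many low-prevalence
features become dense at |S| ≥ 0.2; interpret hub structure through ranks
(see `eigenvector_rank()`) rather than absolute edge counts.

The conditional-dependence network estimates a sparse precision matrix by
graphical lasso (blockwise coordinate descent, implemented in C++ in this
package) on z-scored CLR features, with the penalty chosen by 5-fold
cross-validation over a 20-point logarithmic grid. The selection rule is
the **one-standard-error rule**: the sparsest penalty whose held-out
log-likelihood is within one SE of the optimum. Maximising CV likelihood
alone systematically over-selects edges (a well-documented property of the
estimator — small spurious partial correlations improve predictive
likelihood), which is the wrong trade-off when the estimand is the edge
set; `rule = "max"` restores the plain CV optimum. Edge weights are
regularised partial correlations `-P_uv / sqrt(P_uu P_vv)`; entries with
|P_uv| ≤ 1e-8 (numerical zero, `min_partial_corr`) are not edges.

Centralities (degree, betweenness, closeness, eigenvector) are computed on
the unweighted topology by default (`weighted = TRUE` uses |weight| as
strength and 1/|weight| as path length). Closeness is computed within each
connected component and scaled by component size (Wasserman–Faust);
eigenvector centrality is normalised to max = 1 and defined as 0 on an
edgeless graph. Networks and centralities are built independently per
storage temperature (`per_condition_networks()`; strata under 4 samples are
skipped with a message).

## Microbiome–metabolome concordance

`procrustes_m2()` centres both ordinations, scales each to unit sum of
squares, applies the optimal rotation/reflection, and reports the symmetric
Procrustes residual M² in [0, 1] (0 = perfect concordance). Significance
(`procrustes_permutation_test()`, default 1000 permutations) permutes the
rows of the **second** configuration — fixed by convention to the
metabolome so runs are reproducible; the statistic is near-symmetric in
which side is permuted. `stratified_concordance()` runs the test globally
and within each temperature and day stratum (strata under 4 samples
skipped), with the metabolome ordination configurable as PCoA of
Bray–Curtis on TSS, PCA of TSS, or PCA of z-scores. Comparisons use the
first `k_axes = 2` axes, matching how 2-D ordinations are read.

## Differential abundance and the enriched/outcompeted log-ratio

The package consumes externally computed differential-abundance tables
(taxon, condition, logFC, q — e.g. from a bias-corrected compositional
model) via `read_da_table()`; it deliberately does not re-implement such
models. `naive_clr_da()` is a transparent stand-in with the same contract
(mean CLR difference versus the reference condition, Welch tests, BH), and
is labelled as performing no bias correction.

`classify_enriched_outcompeted()` thresholds log-fold changes (conventional
cuts: 0.75 for 16S, 0.1 for ITS); `sample_logratio()` then tracks, per
sample, the log of the geometric mean of enriched taxa over outcompeted
taxa. Zeros inside geometric means are handled either by a pseudocount
(default: half the smallest non-zero value in the table) or by dropping
zero taxa (`zero_handling = "drop"`); samples where a whole set is zero are
flagged `NA` with a warning, never silently filled. The statistic is
invariant to per-sample scaling and antisymmetric under swapping the sets
(both property-tested).

## Metabolite dynamics

The FIA-MS downstream chain is: prevalence filter (≥ 3 samples) →
z-scoring → per-temperature one-way ANOVA across time points at raw
α = 0.05 (a feature is kept if responsive in ≥ 1 temperature; the α is
deliberately uncorrected — this is a screening filter, not an inference) →
k-means on feature trajectories. `select_k()` votes across silhouette,
WCSS elbow (largest second difference) and the gap statistic
(`cluster::clusGap`, B = 20 uniform reference sets over each dimension's
range, first-SE-max rule); majority wins, ties go to the smallest k.
k-means uses 50 restarts (25 inside the k-scan) and restarts on empty
clusters. Per-cluster Kruskal–Wallis tests compare temperatures per day on
pooled member-feature values (groups under 3 observations skipped), BH
within cluster. `class_enrichment()` compares each metabolite class in a
phase × temperature cell (labels like `"4.1"` = phase 1 at 4 °C) against
all other samples: enrichment is `ln(cell mean / global mean)` and
significance a two-sided Mann–Whitney U with tie correction, BH over the
enrichment table. `mass_annotate()` matches observed m/z against a
reference table within ±0.002 Da, all hits reported nearest-first; the
bundled table is a small fermentation-relevant set of monoisotopic masses
for examples and tests, not a substitute for a curated database.
`daywise_anova_tukey()` applies per-day one-way ANOVA across temperatures
with Tukey HSD post hoc, BH across days, and reports Levene's test
alongside as a variance-homogeneity diagnostic.

BH families, explicitly: within-cluster for the Kruskal–Wallis tables,
whole-table for class enrichment, across days for the day-wise ANOVAs, and
across the within-stratum tests of one nested-PERMANOVA call.

## Supervised storage-phase classification

`build_design()` concatenates omics layers over shared samples with
per-feature provenance; targets are day, temperature, or their phase ×
temperature cross (9 classes in the default design).
`rf_cross_validate()` runs a nested pipeline inside stratified 5-fold CV:
a 100-tree random forest ranks features by impurity importance on the
training fold only, features above the median importance are kept, a
second forest is refit on them, and held-out samples are scored. Keeping
selection inside folds is what prevents leakage; the suite verifies this
with a label-leak canary. The headline metric is the macro-averaged
one-vs-rest AUC on predicted class probabilities; per-fold AUCs are
averaged (and the pooled out-of-fold AUC is also reported, since both
conventions exist). Per-fold seeds derive deterministically from the
global seed. Importances are the first-stage impurity importances averaged
over folds, carrying provenance so the share of, e.g., metabolite features
among the top 25 is a one-liner (`top_features_report()`).

## The synthetic experiment and its ground truth

`simulate_experiment()` generates the full design with known truth:

* **Bacteria**: relative abundances are a softmax of per-taxon linear
  predictors `b_k + r_k · day · g(T) · effect_size`, with the warmth ramp
  `g(T)` scaled to [0, 1] over the temperature range. At the coldest
  temperature the community is static — cold storage preserves it — while
  warmth drives a succession crossover: the cold specialist (dominant
  baseline, `r < 0`) collapses and the warm specialist (`r > 0`,
  acetic-acid-bacterium-like) expands. Counts are multinomial draws at
  depth 380. This is a phenomenological stand-in chosen to reproduce the
  qualitative crossover with few parameters, not a fermentation kinetics
  model.
* **Fungi**: same machinery with a strongly dominant taxon (softmax
  baseline 6), giving a ≥ 97% mean share near-monoculture; depth 3500.
* **Metabolites**: 150 features split over three planted temporal
  archetypes on the log-intensity scale — (0) flat when cold, rising with
  warmth and time; (1) a mid-storage surge at 30 °C, delayed at 17 °C,
  depleted at 4 °C; (2) depletion under warmth (carbohydrate-like) —
  with per-feature baselines, amplitude jitter and Gaussian noise
  (`noise_sd = 0.5` on amplitudes of ~2 z-units; a clear but not sterile
  signal-to-noise regime).
* **Covariates**: pH, TTA, CFU, sugars, ethanol and acetic acid are
  deterministic functions of the warm-specialist trajectory plus noise
  (acidification tracks the bloom; sugars deplete with warm storage time).
* All randomness flows through one seed; the ground-truth ledger records
  taxon parameters, metabolite cluster labels and per-phase mean shifts.

`simulate_null_dataset()` produces balanced, effect-free designs for
calibration; `simulate_network_dataset()` plants a sparse, diagonally
dominant precision matrix (edge magnitudes 0.3–0.6, random sign; diagonal
1 + absolute row sum, hence positive definite) and draws multivariate
normal samples, defining ground-truth conditional edges.

What passing on this benchmark does **not** show: real amplicon data add
compositional artifacts of upstream denoising, taxonomy collapsing and
library-size variation; real FIA-MS features are heavily correlated within
chemical classes, drift with batch, and are not Gaussian around smooth
archetypes; covariates couple to more than one taxon. Results on the
synthetic design validate the machinery and its conventions, not effect
sizes on any real system.

## Numerical choices and degenerate inputs

Permutation p-values are floored at `1/(n_perm + 1)` and deterministic
under a seed. CLR requires strictly positive input and instructs the user
to replace zeros rather than doing it silently. TSS refuses all-zero
samples by name. The graphical lasso declares non-convergence instead of
returning a stale iterate; its p = 2 closed form (soft-thresholding of the
off-diagonal covariance) anchors the tests. Eigenvector centrality uses
the dominant eigenvector with max-normalisation. k-selection falls back to
the smallest candidate k when the gap rule points below the range. The
day-wise ANOVA skips days lacking 2 temperatures with 2 replicates;
Levene's test on 2-replicate groups can be a perfect fit and is reported
as a diagnostic only.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the default 99-sample
design end to end; Monte-Carlo calibrations use 500 null replicates
(n = 30; 200 for the Procrustes test and for the Kruskal–Wallis wrapper at
n = 60); edge recovery uses p = 20, n = 500 over 5 seeds; archetype
recovery 20 seeds; classification 10 seeds. These sizes were chosen so the
whole suite runs comfortably on one CPU while keeping Monte-Carlo standard
errors around 1 point.

## Known limitations

* The co-occurrence score's 0.2 cut is not scale-calibrated for CLR data
  with heavy zero-replacement; prefer `top_q` when comparing networks
  across feature sets of different prevalence structure.
* CV-selected graphical-lasso supports are imperfect even with the 1-SE
  rule at n = 500, p = 20 (edge-recovery F1 ≈ 0.7–0.85 across seeds on the
  planted benchmark, as recomputed by `scripts/acceptance.R`); treat edge
  lists as hypotheses, not discoveries.
* `naive_clr_da()` ignores sampling-fraction bias by construction; use a
  bias-corrected external model for real data and feed its table in.
* Procrustes concordance compares 2-D summaries by default; structure
  beyond the leading axes is invisible at `k_axes = 2`.
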