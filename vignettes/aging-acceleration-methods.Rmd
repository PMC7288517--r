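---
title: "Modelling accelerated aging in late-onset Parkinson's disease"
author: "AgingAccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling accelerated aging in late-onset Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AgingAccel)
```

## The scientific problem

Late-onset Parkinson's disease (LOPD, onset at age 50 or later) is widely
viewed as a disease of accelerated aging: aged brains are far more
susceptible, and many of its cellular hallmarks (mitochondrial decline,
apoptosis, chronic neuroinflammation) overlap with normal brain aging.
`AgingAccel` implements a transcriptomic pipeline for making that idea
quantitative on bulk expression cohorts that contain healthy young
(< 50 y), healthy old (>= 50 y) and LOPD samples:

1. **Marker discovery.** Genes are ranked by the absolute Pearson
   correlation of their expression with a binary phenotype (young/old for
   aging, control/PD for disease), and a cosine-distance k-nearest-neighbour
   classifier (k = 5) is built on the top-n genes for every candidate
   n up to 100. Ten-fold cross-validation selects n; the selected genes are
   the *aging markers* and *PD markers*.
2. **The improved PD predictor.** Before ranking, every old/PD sample can
   be replaced by the residual of the regression of its gene vector on the
   top three principal components of the healthy young samples. Covariation
   that is already present in young people — global co-expression modules,
   shared technical structure — cannot then drive the disease classifier,
   which sharpens it toward genuinely disease-associated signal. The
   untransformed variant ("traditional") is kept for comparison.
3. **Aging scores.** Chronological age is squashed through a sigmoid,
   `t(age) = 1 / (1 + exp(-(age - 50) / 50))`, and regressed on the aging
   markers. A sample's predicted transformed age is its *aging score*; PD
   samples scoring above controls of the same age class exhibit
   accelerated aging. Kruskal-Wallis tests compare the two groups within
   each age threshold (>= 50, >= 55, ..., >= 85).
4. **The aging-acceleration network.** For every gene pair, the Pearson
   correlation and the first-order partial correlation given the aging
   score are computed separately in controls and PD. An edge is retained
   when both absolute between-group differences exceed 0.5 under a BH-FDR
   significance gate. The network is replicated on a held-out partition and
   the two edge sets are compared with Fisher's exact test; a log-log
   degree-frequency regression checks the scale-free signature.
5. **Aging-PD paths.** Shortest paths from every aging marker to every PD
   marker are traced through the network; marker pairs whose correlation
   flips sign between groups are retained, per-marker linkage sums
   highlight the most connected markers, and genes are ranked by *path
   betweenness* (the number of marker paths passing through them), with a
   permutation null obtained by re-drawing random marker sets.
6. **Enrichment.** Each path's genes are tested against GMT gene sets with
   the hypergeometric upper tail, BH-adjusted across sets within the path
   (pass: p < 0.05 and FDR < 0.1).

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `k` | 5 | kNN neighbours (cosine distance) |
| `folds` | 10 | CV folds for feature-count selection |
| `max_features` | 100 | largest candidate marker-list size |
| `test_fraction` | 1/3 | held-out share of the 2:1 split |
| `age_cut` | 50 y | young/old boundary; early-onset PD (< 50 y) removed |
| `sigmoid_center`, `sigmoid_scale` | 50, 50 y | age-sigmoid midpoint/width |
| `zero_fraction` | 0.30 | genes with >= 30% zeros are dropped |
| `n_components` | 3 | SVD components removed per block; young PCs removed |
| `delta_threshold` | 0.5 | minimum absolute correlation difference (both plain and partial) |
| `fdr_threshold` | 0.05 | BH gate on the four per-edge coefficient tests |
| `perm_reps` | 1000 | betweenness permutation replicates |
| `enrich_p`, `enrich_fdr` | 0.05, 0.1 | enrichment pass thresholds |

All of these are surfaced in `pipelineConfig()` and default to the values
above.

## What the synthetic cohort emulates

Real multi-study cohorts of this design are assembled from several
microarray platforms and carry strong structured covariation. The
generator (`generateCohort()`) plants, in order:

* **Ages and platforms** — young ages uniform on 20–49, old/PD on 50–95;
  samples assigned uniformly to five platforms, with an additive
  per-(gene, platform) Gaussian offset (`platform_shift_sd`, default 0.5).
  The per-platform normalization is expected to remove this entirely.
* **Global co-expression factors** — three latent factors with N(0, 1)
  loadings on every gene. These stand in for the dominant
  transcriptome-wide modules of real data. They matter mechanistically: a
  uniform disease mean shift is a rank-1 component of the PD block, and
  the rank-3 SVD step of the normalization removes the top three
  components of each block. Without stronger structure above it, the
  disease signal itself would be stripped. With the factors occupying the
  top components — as in real data — the SVD step removes nuisance, and
  the young-PC residualization removes the same factor structure from the
  old/PD samples, which is exactly why the improved PD predictor
  outperforms the traditional one on this cohort.
* **Aging genes** — mean linear in the sigmoid-transformed age. The slope
  `aging_effect` is expressed per standard deviation of the cohort's
  transformed age (the raw sigmoid only spans ~0.1 SD units across a
  cohort, so an unstandardized slope of practical size would plant an
  undetectably small group separation).
* **PD genes** — a constant `pd_effect` shift in PD samples.
* **Differential pairs** — for each planted pair, a shared pair-level
  latent with loading `+a` on both genes in controls and `-a` on the
  second gene in PD, `a` scaled against the total background variance so
  the realized within-pair correlation is about `+rho` in controls and
  `-rho` in PD. This produces exactly the "opposite sign" pairs the
  bipartite stage retains.

What the generator deliberately does **not** emulate: probe-level
intensities, platform annotation files, non-Gaussian count noise,
missing-not-at-random dropout, age-dependent covariance changes, or any
real co-expression topology. Passing recovery tests therefore show that
the pipeline's statistics behave as designed under their own model
assumptions — not that the biological findings of any particular cohort
would be reproduced.

## Numerical and design choices

* **Probe collapse** uses the arithmetic per-sample mean of a symbol's
  probes.
* **Normalization step 1** z-scores *all* samples of a platform against
  the platform's normal-sample mean/SD. Standardizing only the old/PD
  samples would leave the platform offset inside the young block (the
  final z-score subtracts old-normal statistics that are already in
  z-units), defeating batch removal for the aging task.
* **SVD removal** subtracts the rank-3 truncated-SVD reconstruction of the
  old-normal and PD blocks separately, per platform, with no extra
  centering; an exactly rank-3 block is annihilated. Genes whose reference
  SD is (numerically) zero get z-scores of 0 with a warning rather than
  NaN.
* **Feature ranking inside CV folds** is the default (no selection
  leakage); `rankOnce = TRUE` reproduces the single-ranking variant.
  Constant genes get r = 0 and rank after all informative genes; rank ties
  break lexicographically by gene id.
* **kNN conventions**: distance ties break by training-sample index; even
  vote ties (impossible at k = 5) go to class 0; zero-norm vectors are
  assigned cosine distance 1 to everything. Vote fractions are the ROC
  scores; the AUC is the trapezoid area of the step curve.
* **Aging score**: `fitAgingScore()` defaults to the literal no-intercept
  regression. On normalized data the markers are mean-zero, and a
  no-intercept fit cannot represent the mean transformed age (~0.52); it
  instead projects the constant onto noise and destroys the score-age
  correlation. `runPipeline()` therefore fits with an intercept by default
  (`score_intercept = TRUE`), and fits on normal samples only
  (`score_fit_group = "normal"`), applying the model to everyone.
  Under-determined systems return the minimum-norm solution with a
  warning.
* **Network gate**: BH runs within each of the four coefficient families
  (r and partial r, in controls and PD); an edge passes the gate when any
  family's q-value is below 0.05 (`significance_mode = "any"`; `"all"` and
  `"off"` are available). The delta rule is strict (`> 0.5`). Degenerate
  partial correlations (covariate perfectly correlated with a gene) are
  set to 0 with p = 1.
* **Shortest paths** are computed on the unweighted graph (breadth-first
  distances); among equal-length paths the lexicographically smallest node
  sequence is returned, making betweenness counts reproducible. An
  `all_shortest_paths`-style fractional count is deliberately not the
  default: one path per marker pair matches betweenness-as-path-count.
* **Permutation p-values** default to the plain proportion
  `count / reps`, which can be exactly 0. Because path betweenness is
  heavily tied at 0, that estimator is super-uniform under the null;
  `estimator = "randomized"` (tie-broken, exactly uniform under
  exchangeability) is provided for calibration checks, and `"smoothed"`
  gives the (count+1)/(reps+1) variant. Permutation endpoints are drawn
  from network nodes (paths require membership).
* **Enrichment** uses the standard hypergeometric denominator `C(N, n)`
  (the printed form of the source formula divides by `C(N, k)`, which does
  not normalize); the universe defaults to the union of the GMT members
  and BH runs within each path (`bhScope = "global"` is available).
* **Retention of aging-PD pairs** uses the strict sign rule
  (`r_control * r_pd < 0`); the absolute difference is reported but not
  thresholded.

## Problem sizes used by the test-suite

The packaged tests and the acceptance script run entirely on synthetic
cohorts. Cohort-level checks use the study-scale composition (425 young,
447 old-normal, 392 PD across five platforms) with 300 genes; edge
recovery uses 300 genes with 150 samples per group and 20 planted pairs
over 10 seeds; null calibration uses 20 zero-signal seeds; permutation
calibration uses 300 random 24-node graphs at 60 replicates each. These
sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick on a laptop.

## Known limitations

* All-pairs correlation is quadratic in gene count;
  `network_max_genes` (default 2000) guards the desk-scale path, and
  genome-wide runs (~14k genes) are cluster-scale.
* The differential network at desk-scale sample sizes acquires some false
  edges through the per-block SVD step itself (removal is estimated
  separately per group, so its noise is differential); they are reported,
  not suppressed.
* On sparse desk-scale networks most aging-PD marker pairs are
  unconnected, so path betweenness and per-path enrichment are often
  degenerate there; those stages are exercised on constructed graphs in
  the test-suite.
* The binary age-class coding (young/old at 50) follows the study design;
  no continuous-age classifier is provided.
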