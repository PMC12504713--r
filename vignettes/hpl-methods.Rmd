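---
title: "Methods: histomorphological phenotype analysis with hplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histomorphological phenotype analysis with hplearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mesothelioma is a morphologically heterogeneous tumour whose histological
subtype (epithelioid vs the pooled biphasic/sarcomatoid "non-epithelioid"
class) and outcome are usually judged from whole-slide images (WSIs) by
expert pathologists. Histomorphological phenotype learning (HPL) replaces
that manual step with an unsupervised pipeline: WSIs are cut into tiles, a
self-supervised encoder turns each tile into a D-dimensional embedding
(D = 128 by convention), and recurring tissue morphologies are found as
clusters of those embeddings — histomorphological phenotype clusters
(HPCs). Each slide or patient is then a *composition*: the fraction of its
tiles in each HPC. Those compositions, after a log-ratio transform, feed
ordinary interpretable statistics — logistic regression for subtype, Cox
regression for survival, correlation screens against molecular signatures.

`hplearn` implements everything downstream of the encoder. It consumes a
tile table (ids plus embedding coordinates) and a clinical table, and never
touches images. Because the motivating imaging cohorts are access-restricted,
the package ships a synthetic-data generator whose ground truth makes every
stage verifiable at desk scale.

## The synthetic generator

`simulate_cohort()` draws tile embeddings from an isotropic unit-variance
Gaussian mixture. Centroids are placed on orthogonal axes scaled so each
pair is exactly `component_separation` apart (in units of the
within-component standard deviation); separation is therefore a single
interpretable knob for cluster difficulty. Each patient owns a composition
drawn from a symmetric Dirichlet, slides draw tile components i.i.d. from
it, so slides of one patient share the patient's composition — the real
within-patient slide-to-slide variation in HPC content is *not* modelled,
and tests deliberately avoid asserting anything about slide-level variance.

Clinical outcomes are driven by the clr (centred log-ratio) coordinates of
the *true* composition so that generator and fitted models share a
parameterisation and coefficient-recovery tests are meaningful:

* subtype: non-epithelioid with probability
  `plogis(b0 + sum(effects * clr(A)))`; the default intercept −1.1 gives
  the roughly 1:3 non-epithelioid:epithelioid imbalance typical of surgical
  series (the non-epithelioid half is split evenly into biphasic and
  sarcomatoid labels);
* survival: exponential event times with rate
  `baseline_hazard * exp(sum(effects * clr(A)))`; the default baseline
  0.045/month corresponds to a median survival near 15 months at zero
  effects, a realistic figure for resected mesothelioma;
* censoring: an independent uniform administrative censoring time
  `C ~ U(0, tau)`, with `tau` solved numerically so the expected censored
  fraction matches the configured target. Uniform-entry censoring keeps the
  exponential likelihood tractable for closed-form oracles.

All randomness flows from one master seed through named substreams
(`centroids`, `tiles`, `survival`, ...), so adding a generator call never
perturbs other outputs and identical configurations are byte-identical.

What the generator does *not* emulate: stain and scanner variation, spatial
tile adjacency, non-Gaussian cluster shapes, informative censoring, and any
coupling between subtype and survival beyond what shared compositions
induce. Passing tests therefore certify the statistical machinery, not
performance on real slides.

## HPC discovery

Discovery follows the standard single-cell-style recipe: subsample
reference tiles (uniform within each slide, so large slides cannot
dominate), build a k-nearest-neighbour graph (Euclidean, k = 15 by default,
directed neighbour lists mutualised by union), and run Leiden community
detection with the modularity objective across a resolution sweep
(default 0.5, 1, 1.5, 2). The sweep table reports cluster counts and
modularities; by default the highest-modularity run is kept, or the run
closest to a requested cluster count. The reference subsample default is
desk-scale (50,000); production HPL analyses use an order of magnitude
more.

Remaining tiles are assigned by a majority vote among their m = 25 nearest
reference tiles, the natural instance-based reading of "assign by
distance"; a nearest-centroid alternative is available behind a flag.
Determinism rules: distance ties break toward the lower row index,
assignment vote ties toward the smaller HPC id, a tile exactly coinciding
with a reference tile inherits that reference's label (so reference tiles
always reproduce their own labels), and cluster labels are renumbered
0-based by decreasing size. Cluster counts generally grow with resolution
but Leiden offers no guarantee; the sweep simply reports what it found.

## Compositions and the clr transform

Per-slide (or tile-pooled per-patient) compositions live on the c-part
simplex. Slides with fewer than `min_tiles = 100` tiles are dropped before
aggregation, mirroring the usual exclusion of sparsely tiled WSIs. An HPC
is "present" in a case when its fraction strictly exceeds 1%, and
prevalence bands follow the rare (< 20%), intermediate (20–80%),
ubiquitous (> 80%) convention.

Zeros are replaced multiplicatively — zero parts become delta, non-zero
parts shrink by `1 − delta·(#zeros)` — with a count-aware default
`delta = 0.5 / n_tiles` (half a tile's worth of frequency), since the
literature the method follows cites the replacement strategy but not a
delta. The clr transform uses the natural logarithm; the base cancels in
every downstream linear model but is fixed for reproducibility. clr
coordinates sum to zero by construction, an exact collinearity every
downstream model must absorb.

## Subtype and survival models

Both models run at patient level on clr coordinates (the subtype model can
also run per-WSI with patient labels; folds are patient-disjoint either
way). The zero-sum collinearity is handled two ways, matching the two uses
of each model:

* the *predictive* fit keeps all c coordinates with a tiny ridge penalty
  (1e-6) — symmetric in the HPCs, and the penalty is far too small to
  shrink estimates materially;
* the *inferential* fit drops one reference HPC (the last, by default) and
  maximises the unpenalised likelihood, yielding per-HPC log-odds or
  log-hazard ratios with Wald 95% intervals and p-values, plus a
  likelihood-ratio test against the intercept-only model for the logistic
  case.

Class imbalance is addressed with Edited Nearest Neighbour undersampling
(k = 3): majority-class training samples whose neighbourhood vote
contradicts their label are removed, inside training folds only.
Sensitivity and specificity are reported at the 0.5 probability threshold.
Perfect separation in the logistic fit is caught and reported with
penalised estimates in place of Wald inference.

The Cox model uses Efron tie handling (the common default; duplicating a
dataset therefore shifts estimates very slightly by creating ties, which
the tests acknowledge). Risk stratification freezes the median linear
predictor of the training fold; held-out patients strictly above it are
"high risk". The 60-month horizon applies only to Kaplan–Meier display and
the log-rank test (later events are censored at the horizon), never to
model fitting. Harrell's concordance counts prediction ties as 1/2 and is
checked against a brute-force all-pairs oracle. Per-patient decision
contributions are `beta_i * (x_i − baseline_i)`; for a linear model these
are exactly the Shapley values and sum to the difference in linear
predictors.

## Rater agreement

Multi-rater HPC annotations arrive as item-by-category count tables with a
constant rater count n. Majority consensus reports the modal category with
unanimity and complete-disagreement flags; modal ties are left unresolved
rather than broken arbitrarily. Fleiss' kappa follows the textbook
formulas; rows with missing raters must be excluded beforehand because the
statistic assumes constant n. Kappa values are not comparable across
annotation components with different category counts — more categories
mechanically lower chance agreement — so the package reports kappa per
component and never averages across them.

## Attention-based multiple-instance learning

For bag-level classification (tissue-microarray cores as bags of tile
embeddings) the package implements attention pooling: instance scores
`w' tanh(V h_k)`, softmax attention weights, pooled representation
`z = Σ a_k h_k`, and a linear classifier on z trained with binary
cross-entropy. The plain (non-gated) form is the default; a `gated` flag
multiplies the tanh branch by a sigmoid gate. Gradients are analytic and
verified against finite differences.

Optimisation choices, made once for the desk-scale problem sizes: Adam at
learning rate 1e-3, one bag per step, up to 50 epochs with early stopping
on held-out-bag AUC (ties keep the more-trained parameters, since a small
validation set saturates long before convergence). The attention score
vector w starts at zero so training begins as mean pooling and the
classifier can find the informative direction before attention sharpens;
because the loss surface is still non-convex and an occasional seed
converges to an attention pattern that ignores the signal tiles (visible
as a training loss an order of magnitude above successful runs), up to
three seeded restarts are attempted and the best run kept. Attention
quality is summarised as the enrichment of attention mass on ground-truth
signal tiles relative to uniform 1/K attention.

## Association screening

Compositions (clr coordinates or raw proportions — both appear in
practice: proportions for core-level IHC-style analyses, clr for WSI-level
transcriptome-style analyses) are correlated column-by-column against
signature matrices with two-sided Pearson or Spearman tests,
pairwise-complete over missing values, with constant columns reported as
NA rather than silently correlated. Spearman p-values are exact for n ≤ 9
without ties. Retention offers both conventions found in practice: a raw
`p < alpha` threshold (default 0.01) and Benjamini–Hochberg step-up FDR
(default alpha 0.05); BH-adjusted p-values are reported in either mode.

## Problem sizes and numerical choices

The test suite and the acceptance script use fixed desk-scale conditions
chosen once: 20,000 tiles / 10 components / 128 dimensions / 6-sigma
separation with a 5,000-tile reference subsample for clustering recovery;
400 patients with clr-scale effects ±1.5 (subtype) and ±0.8 (survival,
20% censoring); 200 bags of 50 tiles with 10% signal tiles shifted by
4 sigma (16 dimensions); 47 items × 3 raters for agreement; 20 seeds for
null-calibration checks. Tolerances: simplex closure and clr zero-sum to
1e-9, linear-identity checks to 1e-10, oracle equivalences exact or to
1e-12, statistical recovery thresholds as stated in the tests.

## Known limitations

* The generator's slides inherit their patient's composition exactly;
  slide-level compositional variance is untested.
* Leiden resolution selection by modularity can over- or under-split when
  mixture components overlap heavily; the sweep table and
  `target_clusters` exist precisely so users can inspect and override.
* The MIL module is a reference implementation in plain R: adequate for
  hundreds of bags, not for tens of thousands.
* No multiclass subtype model, competing risks, time-varying covariates,
  isometric log-ratio coordinates, or spatial statistics; these are out of
  scope by design.
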