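# hplearn

Downstream analysis for **histomorphological phenotype learning (HPL)** in
mesothelioma pathology. HPL pipelines tile whole-slide images, embed each
tile with a self-supervised encoder, and discover recurring tissue
morphologies — *histomorphological phenotype clusters* (HPCs) — as
communities of tile embeddings. `hplearn` implements everything after the
encoder, for pathologists and computational biologists who have per-tile
embedding vectors and clinical tables but not (or not only) the images:

* **HPC discovery** — k-nearest-neighbour graph over a slide-stratified
  tile subsample, Leiden community detection across a resolution sweep,
  and majority-vote assignment of the remaining tiles
  (`fit_hpc_model()`, `assign_remaining()`).
* **Compositional analysis** — per-slide / per-patient HPC compositions
  `A = (a_0, …, a_{c−1})` with `Σ a_i = 1`, presence (`a_i > 1%`) and
  prevalence bands, multiplicative zero replacement, and the centred
  log-ratio transform `clr_i = log a_i − mean_j log a_j`
  (`compute_composition()`, `composition_clr()`).
* **Subtype classification** — logistic regression
  `P(non-epithelioid) = plogis(b0 + b1·clr(A))` with Edited Nearest
  Neighbour undersampling, patient-disjoint 5-fold cross-validation, and
  per-HPC log-odds ratios with Wald intervals
  (`fit_subtype()`, `cross_validate_subtype()`).
* **Survival analysis** — Cox proportional hazards on patient clr vectors,
  Harrell's concordance, median-predicted-hazard risk groups,
  Kaplan–Meier curves with log-rank tests at a 60-month horizon, and exact
  per-HPC additive decision contributions
  (`fit_cox()`, `cross_validate_cox()`, `km_logrank()`).
* **Rater agreement** — majority consensus with unanimity /
  complete-disagreement flags and Fleiss' kappa
  `κ = (P̄ − P̄_e)/(1 − P̄_e)` (`majority_consensus()`, `fleiss_kappa()`).
* **Attention-MIL** — gated/plain attention pooling
  `a_k = softmax_k(wᵀ tanh(V h_k))`, `z = Σ a_k h_k`, over bags of tile
  embeddings (tissue-microarray cores), with bag-disjoint cross-validation
  (`train_mil()`, `attention_pool()`).
* **Signature association** — Pearson/Spearman screens of HPC compositions
  against molecular signature scores with raw-threshold or
  Benjamini–Hochberg retention (`correlate()`, `filter_and_adjust()`).
* **Synthetic data with ground truth** — a seeded generator
  (`simulate_cohort()`, `simulate_bags()`, `simulate_ratings()`,
  `simulate_signatures()`) that plants known clusters, effect sizes,
  censoring and agreement levels, so every stage above is verifiable
  without access to restricted cohorts.

## Worked example

A synthetic cohort with two planted subtype drivers (log-odds ±1.5 on
HPCs 1 and 4 per clr unit) and two survival drivers (log-hazard ±0.8 on
HPCs 0 and 3), run end to end:

```r
library(hplearn)

cfg <- synthetic_config(
  seed = 42, n_patients = 200, n_components = 6, dim = 32,
  slides_per_patient = c(1, 2), tiles_per_slide = c(120, 180),
  subtype_drivers = c("1" = 1.5, "4" = -1.5),
  survival_drivers = c("0" = 0.8, "3" = -0.8),
  censoring_fraction = 0.2)
sim <- simulate_cohort(cfg)                     # 46,809 tiles, 200 patients

model <- fit_hpc_model(sim$tiles, subsample = 3000, k = 15, seed = 42)
model
#> HPC model: 6 clusters at Leiden resolution 0.5 (3000 reference tiles, k = 15)

emb <- as.matrix(sim$tiles[grep("^e[0-9]+$", names(sim$tiles))])
rownames(emb) <- sim$tiles$tile_id
asg <- data.frame(sim$tiles[c("tile_id", "slide_id", "patient_id")],
                  hpc = unname(assign_remaining(model, emb)))

comp <- compute_composition(asg, "patient", model$n_clusters)
comp
#> HPC compositions: 200 patient(s) x 6 HPCs (median 262 tiles/sample)
clr <- composition_clr(comp)                    # zero-replaced, clr-transformed

y <- binarize_subtype(sim$patients[match(rownames(clr),
                                         sim$patients$patient_id), ])
round(cross_validate_subtype(clr, y, folds = 5, seed = 42)$mean, 3)
#>           auc avg_precision   sensitivity   specificity
#>         0.866         0.838         0.838         0.758

idx <- match(rownames(clr), sim$patients$patient_id)
cvx <- cross_validate_cox(clr, sim$patients$time_months[idx],
                          sim$patients$event[idx], seed = 42)
round(cvx$mean, 3)
#> [1] 0.776
km <- km_logrank(cvx$held_out$group, cvx$held_out$time, cvx$held_out$event)
c(chisq = round(km$chisq, 1), p = signif(km$p, 3))
#>    chisq        p
#> 9.23e+01 7.28e-22
```

The generator planted six well-separated embedding clusters; Leiden
recovers all six, the cross-validated AUC of 0.87 reflects the two planted
subtype drivers, and the median-hazard split of held-out patients
separates survival sharply (log-rank χ²(1) = 92.3). `run_pipeline()` wraps
the same flow with CSV artifacts and a reproducibility manifest.

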