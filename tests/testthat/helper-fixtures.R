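# Shared fixtures: small seeded cohorts and bags built in code.

small_cohort <- function(seed = 3, n_patients = 120, n_components = 8,
                         dim = 12, subtype_drivers = numeric(0),
                         survival_drivers = numeric(0),
                         censoring_fraction = 0.2) {
  simulate_cohort(synthetic_config(
    seed = seed, n_patients = n_patients, n_components = n_components,
    dim = dim, slides_per_patient = c(1, 2), tiles_per_slide = c(110, 160),
    subtype_drivers = subtype_drivers, survival_drivers = survival_drivers,
    censoring_fraction = censoring_fraction
  ))
}

# clr of the generator's true patient compositions (strictly positive a.s.)
truth_clr <- function(sim) clr_transform(sim$truth$patient_composition)

# Mann-Whitney rank AUC: the independent oracle for the package's AUC metric.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random strictly positive composition matrix (rows sum to 1)
random_compositions <- function(n, c, seed, zero_fraction = 0) {
  set.seed(seed)
  A <- matrix(rgamma(n * c, 1), n, c)
  if (zero_fraction > 0) {
    z <- matrix(runif(n * c) < zero_fraction, n, c)
    keep_one <- cbind(seq_len(n), max.col(A))
    z[keep_one] <- FALSE
    A[z] <- 0
  }
  A / rowSums(A)
}
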