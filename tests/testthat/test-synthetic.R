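test_that("empty cohort returns empty tables with intact schemas", {
  sim <- simulate_cohort(synthetic_config(seed = 1, n_patients = 0, dim = 8))
  expect_equal(nrow(sim$tiles), 0)
  expect_equal(names(sim$tiles)[1:3], c("tile_id", "slide_id", "patient_id"))
  expect_true(all(paste0("e", 0:7) %in% names(sim$tiles)))
  expect_equal(names(sim$patients),
               c("patient_id", "subtype", "time_months", "event"))
  expect_equal(nrow(sim$patients), 0)
})

test_that("config validation rejects bad inputs", {
  expect_error(synthetic_config(component_separation = -1), "separation")
  expect_error(synthetic_config(censoring_fraction = 1.5))
  expect_error(synthetic_config(n_components = 1))
  expect_error(synthetic_config(subtype_drivers = c("9" = 1), n_components = 5),
               "0-based")
})

test_that("widely separated components are recovered by nearest centroid", {
  cfg <- synthetic_config(seed = 7, n_components = 2, dim = 8,
                          n_patients = 2, slides_per_patient = c(1, 1),
                          tiles_per_slide = c(50, 50),
                          component_separation = 10)
  sim <- simulate_cohort(cfg)
  emb <- as.matrix(sim$tiles[paste0("e", 0:7)])
  d2 <- sapply(1:2, function(j) {
    rowSums(sweep(emb, 2, sim$truth$centroids[j, ])^2)
  })
  nearest <- max.col(-d2) - 1L
  expect_equal(unname(nearest), unname(sim$truth$tile_component))
})

test_that("observed censoring matches the configured fraction", {
  sim <- simulate_cohort(synthetic_config(seed = 3, n_patients = 500,
                                          dim = 4, n_components = 4,
                                          tiles_per_slide = c(2, 4),
                                          censoring_fraction = 0.2,
                                          slides_per_patient = c(1, 1)))
  expect_lt(abs(mean(!sim$patients$event) - 0.2), 0.05)
})

test_that("identical configs give identical outputs", {
  cfg <- synthetic_config(seed = 11, n_patients = 20, dim = 6,
                          n_components = 3, tiles_per_slide = c(10, 20),
                          subtype_drivers = c("1" = 1))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("true compositions are on the simplex", {
  sim <- small_cohort(seed = 5, n_patients = 50)
  expect_true(all(abs(rowSums(sim$truth$patient_composition) - 1) < 1e-12))
  expect_equal(length(sim$truth$tile_component), nrow(sim$tiles))
})

test_that("nearest-centroid accuracy is non-decreasing in separation", {
  acc <- sapply(c(0.5, 2, 4, 8), function(sep) {
    sim <- simulate_cohort(synthetic_config(
      seed = 13, n_patients = 5, n_components = 4, dim = 8,
      slides_per_patient = c(1, 1), tiles_per_slide = c(80, 80),
      component_separation = sep))
    emb <- as.matrix(sim$tiles[paste0("e", 0:7)])
    d2 <- sapply(1:4, function(j) {
      rowSums(sweep(emb, 2, sim$truth$centroids[j, ])^2)
    })
    mean(max.col(-d2) - 1L == sim$truth$tile_component)
  })
  expect_true(all(diff(acc) >= 0))
})

test_that("rating simulation respects geometry and perfect agreement", {
  tab <- simulate_ratings(47, 3, 3, agreement_level = 1, seed = 2)
  expect_equal(dim(tab), c(47, 3))
  expect_true(all(rowSums(tab) == 3))
  expect_true(all(apply(tab, 1, max) == 3))
  expect_error(simulate_ratings(10, 1, 3, 0.5), "n_raters")
})

test_that("chance-level rating agreement yields kappa near zero", {
  kappas <- vapply(1:100, function(s) {
    fleiss_kappa(simulate_ratings(40, 3, 4, agreement_level = 1 / 4,
                                  seed = s))$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 0.03)
})

test_that("bag simulation plants the advertised number of signal tiles", {
  bags <- simulate_bags(20, 50, signal_fraction = 0.1, shift = 4,
                        dim = 8, seed = 1)
  pos <- Filter(function(b) b$label == 1, bags)
  neg <- Filter(function(b) b$label == 0, bags)
  expect_true(all(vapply(pos, function(b) sum(b$signal), integer(1)) == 5L))
  expect_true(all(vapply(neg, function(b) sum(b$signal), integer(1)) == 0L))
  expect_error(simulate_bags(10, 0, 0.1, 4), "tiles_per_bag")
})

test_that("a linear probe on bag means separates shifted bags", {
  bags <- simulate_bags(120, 50, signal_fraction = 0.1, shift = 6,
                        dim = 16, seed = 4)
  means <- t(vapply(bags, function(b) colMeans(b$instances), numeric(16)))
  y <- vapply(bags, `[[`, integer(1), "label")
  tr <- seq_len(80)
  fit <- suppressWarnings(glm(y[tr] ~ means[tr, ], family = binomial()))
  score <- cbind(1, means[-tr, ]) %*% coef(fit)
  expect_gt(rank_auc(drop(score), y[-tr]), 0.95)
})

test_that("linked signatures hit the requested correlation", {
  sim <- small_cohort(seed = 9, n_patients = 500)
  sig <- simulate_signatures(sim$patients, sim$truth, n_signatures = 3,
                             linked = data.frame(signature = c(1, 2),
                                                 hpc = c(0, 3),
                                                 rho = c(0.7, 0)),
                             seed = 5)
  clr <- truth_clr(sim)
  expect_lt(abs(cor(sig[, 1], clr[, 1]) - 0.7), 0.1)
  expect_lt(abs(cor(sig[, 2], clr[, 4])), 0.1)
  empty <- simulate_signatures(sim$patients, sim$truth, 0, seed = 1)
  expect_equal(dim(empty), c(500, 0))
  expect_equal(rownames(empty), sim$patients$patient_id)
  expect_error(
    simulate_signatures(sim$patients, sim$truth, 2,
                        linked = data.frame(signature = 1, hpc = 99, rho = 0.5)),
    "unknown HPC")
  expect_error(
    simulate_signatures(sim$patients, sim$truth, 2,
                        linked = data.frame(signature = 1, hpc = 0, rho = 1)),
    "correlations")
})
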