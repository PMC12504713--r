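test_that("concordance follows the pairwise definition", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  expect_error(concordance_index(c(1, 2), c(5, 4), c(0, 0)), "comparable")
})

test_that("concordance equals a brute-force all-pairs oracle", {
  set.seed(12)
  for (rep_ in 1:3) {
    n <- 80
    lp <- round(rnorm(n), 1)                 # rounded: prediction ties occur
    time <- round(rexp(n, 0.1), 1)           # ties in time too
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    expect_equal(concordance_index(lp, time, event),
                 brute_force_cindex(lp, time, event))
  }
})

test_that("random predictors concord at chance level", {
  cs <- vapply(1:50, function(s) {
    set.seed(s + 500)
    concordance_index(rnorm(200), rexp(200, 0.05), rbinom(200, 1, 0.8))
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("cox fit recovers planted log-hazards and ignores duplication", {
  sim <- small_cohort(seed = 51, n_patients = 300,
                      survival_drivers = c("1" = 0.8, "4" = -0.8))
  X <- truth_clr(sim)
  fit <- fit_cox(X, sim$patients$time_months, sim$patients$event)
  tab <- fit$coef_table
  expect_gt(tab$log_hr[tab$hpc == 1], 0)
  expect_lt(tab$log_hr[tab$hpc == 4], 0)
  expect_lt(tab$p[tab$hpc == 1], 0.05)
  expect_lt(tab$p[tab$hpc == 4], 0.05)

  # duplicating every row leaves the partial likelihood essentially
  # unchanged; small shifts remain because duplication creates event-time
  # ties handled by the Efron correction, and because the tiny ridge
  # penalty halves relative to the doubled likelihood
  fit2 <- fit_cox(rbind(X, X), rep(sim$patients$time_months, 2),
                  rep(sim$patients$event, 2))
  expect_equal(fit2$coef_table$log_hr, fit$coef_table$log_hr,
               tolerance = 0.02)
  expect_equal(fit2$beta, fit$beta, tolerance = 0.02)
  expect_error(fit_cox(X, sim$patients$time_months,
                       rep(FALSE, nrow(X))), "no events")
})

test_that("cox null data give small z and chance held-out concordance", {
  sim <- small_cohort(seed = 61, n_patients = 200)
  X <- truth_clr(sim)
  cv <- cross_validate_cox(X, sim$patients$time_months, sim$patients$event,
                           seed = 3)
  expect_lt(abs(cv$mean - 0.5), 0.08)
})

test_that("two-group exponential hazard ratio is reproduced", {
  set.seed(13)
  n <- 4000
  x <- rep(0:1, each = n / 2)
  beta <- 0.7
  time <- rexp(n, 0.05 * exp(beta * x))
  fit <- survival::coxph(survival::Surv(time, rep(1, n)) ~ x)
  # package fit on a 2-column zero-sum design should match the same HR
  X <- cbind(x - 0.5, 0.5 - x)
  pf <- fit_cox(X, time, rep(TRUE, n), reference = 2)
  expect_equal(pf$coef_table$log_hr[1], unname(coef(fit)[1]), tolerance = 0.01)
  expect_lt(abs(pf$coef_table$log_hr[1] - beta) / beta, 0.05)
})

test_that("risk stratification freezes the training median", {
  sim <- small_cohort(seed = 71, n_patients = 100,
                      survival_drivers = c("0" = 1))
  X <- truth_clr(sim)
  fit <- fit_cox(X, sim$patients$time_months, sim$patients$event)
  s1 <- stratify_risk(fit, X)
  s2 <- stratify_risk(fit, X)
  expect_identical(s1, s2)
  expect_equal(sort(as.integer(table(s1$group))), c(50, 50))
  # a patient exactly at the median goes low ("strictly above" rule)
  at_median <- X[which.min(abs(s1$lp - fit$threshold)), , drop = FALSE]
  if (abs(drop(at_median %*% fit$beta) - fit$threshold) < 1e-12) {
    expect_equal(stratify_risk(fit, at_median)$group, "low")
  }
  # planted effect: high-risk group dies sooner
  med <- tapply(sim$patients$time_months, s1$group, median)
  expect_lt(med[["high"]], med[["low"]])
  expect_error(stratify_risk(list(), X), "cox_fit")
})

test_that("log-rank matches a hand computation on six subjects", {
  # groups A, A, A, B, B, B with times 1,3,5 / 2,4,6, all events
  time <- c(1, 3, 5, 2, 4, 6)
  event <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  out <- km_logrank(grp, time, event, horizon_months = Inf)
  # brute-force observed-vs-expected for group A at each event time
  o_e <- function() {
    at_risk <- function(t) c(sum(time >= t & grp == "A"), sum(time >= t))
    O <- E <- V <- 0
    for (t in sort(time[event == 1])) {
      n1 <- at_risk(t)[1]; n <- at_risk(t)[2]; d <- sum(time == t & event == 1)
      O <- O + sum(time == t & event == 1 & grp == "A")
      E <- E + d * n1 / n
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
    }
    (O - E)^2 / V
  }
  expect_equal(out$chisq, o_e(), tolerance = 1e-10)
  expect_equal(out$df, 1L)

  # identical event patterns: statistic near zero
  null <- km_logrank(rep(c("A", "B"), 5), rep(1:5, each = 2), rep(1, 10),
                     horizon_months = Inf)
  expect_lt(null$chisq, 1e-10)
  expect_equal(null$p, 1, tolerance = 1e-6)
  expect_error(km_logrank(grp, time, rep(0, 6)), "no events")
  expect_error(km_logrank(rep("A", 6), time, event), "two")
})

test_that("horizon truncation censors late events for display", {
  out <- km_logrank(rep(c("A", "B"), each = 10),
                    c(seq(5, 50, 5), seq(55, 100, 5)),
                    rep(1, 20), horizon_months = 60)
  sf <- out$survfit
  expect_true(all(sf$time <= 60))
})

test_that("decision contributions are exact Shapley values of the linear model", {
  sim <- small_cohort(seed = 81, n_patients = 50,
                      survival_drivers = c("2" = 0.5))
  X <- truth_clr(sim)
  fit <- fit_cox(X, sim$patients$time_months, sim$patients$event)
  baseline <- colMeans(X)
  x <- X[7, ]
  contrib <- decision_contributions(fit, x, baseline)
  expect_equal(sum(contrib), drop((x - baseline) %*% fit$beta),
               tolerance = 1e-10)
  expect_equal(unname(decision_contributions(fit, baseline, baseline)),
               rep(0, ncol(X)), ignore_attr = TRUE)
  x2 <- baseline; x2[3] <- x2[3] + 1
  expect_equal(sum(decision_contributions(fit, x2, baseline) != 0), 1)
  expect_error(decision_contributions(fit, x[-1], baseline), "length")
})
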