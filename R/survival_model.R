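#' Cox proportional-hazards model on patient clr compositions
#'
#' Fits the partial likelihood with Efron tie handling. As in the subtype
#' module, two fits are kept: a predictive fit with a tiny ridge penalty on
#' all `c` clr coordinates (absorbing the zero-sum collinearity), and an
#' inferential fit with one reference HPC dropped, yielding per-HPC log
#' hazard ratios, 95% confidence intervals and p-values. The median linear
#' predictor of the training data is stored as the frozen risk threshold
#' used by [stratify_risk()].
#'
#' @param X clr coordinate matrix (patients x HPCs).
#' @param time survival/censoring time in months.
#' @param event event indicator (TRUE/1 = death observed).
#' @param penalty ridge penalty (theta of [survival::ridge()], default 1e-6).
#' @param reference 1-based column dropped in the inferential fit.
#' @param subtype optional per-patient subtype labels enabling
#'   `subtype_filter`.
#' @param subtype_filter `"all"` (default), `"epithelioid"`, or
#'   `"nonepithelioid"`: refit on the subgroup only.
#' @param covariates optional numeric data frame of clinical covariates
#'   (e.g. age, stage) appended unpenalised to both fits.
#' @return object of class `cox_fit`: `beta` (length-c predictive
#'   coefficients), `coef_table` (HPC, log HR, CI, p), `threshold` (training
#'   median linear predictor), `reference`, plus the kept row index.
#' @export
fit_cox <- function(X, time, event, penalty = 1e-6, reference = ncol(X),
                    subtype = NULL, subtype_filter = "all",
                    covariates = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (!all(is.finite(X)) || !all(is.finite(time))) stop("non-finite inputs")
  keep <- seq_len(nrow(X))
  if (subtype_filter != "all") {
    if (is.null(subtype)) stop("subtype labels required for subtype_filter")
    nonepi <- binarize_subtype(subtype)
    keep <- which(if (subtype_filter == "epithelioid") nonepi == 0 else nonepi == 1)
    X <- X[keep, , drop = FALSE]
    time <- time[keep]; event <- event[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  event <- as.integer(event)
  if (sum(event) < 1L) stop("no events in the data")

  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  y <- survival::Surv(time, event)

  if (is.null(Z)) {
    pred <- survival::coxph(y ~ survival::ridge(X, theta = penalty, scale = FALSE),
                            ties = "efron")
  } else {
    pred <- survival::coxph(y ~ survival::ridge(X, theta = penalty, scale = FALSE) + Z,
                            ties = "efron")
  }
  beta <- unname(coef(pred)[seq_len(ncol(X))])

  Xr <- X[, -reference, drop = FALSE]
  colnames(Xr) <- paste0("hpc_", (seq_len(ncol(X)) - 1L)[-reference])
  inf_design <- if (is.null(Z)) Xr else cbind(Xr, Z)
  inf <- survival::coxph(y ~ inf_design, ties = "efron")
  sm <- summary(inf)$coefficients
  ix <- seq_len(ncol(Xr))
  est <- unname(sm[ix, "coef"])
  se <- unname(sm[ix, "se(coef)"])
  coef_table <- data.frame(
    hpc = (seq_len(ncol(X)) - 1L)[-reference],
    log_hr = est,
    ci_low = est - qnorm(0.975) * se,
    ci_high = est + qnorm(0.975) * se,
    p = unname(sm[ix, "Pr(>|z|)"])
  )
  beta_cov <- if (is.null(Z)) NULL else unname(coef(pred)[-seq_len(ncol(X))])
  lp <- drop(X %*% beta) + if (is.null(Z)) 0 else drop(Z %*% beta_cov)
  structure(list(
    beta = beta, beta_cov = beta_cov, coef_table = coef_table,
    threshold = median(lp), reference = reference, penalty = penalty,
    subtype_filter = subtype_filter, kept_rows = keep,
    train_lp = lp
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model on %d HPC clr coordinates (%s cases); risk threshold (median lp) = %.3f\n",
              length(x$beta), x$subtype_filter, x$threshold))
  invisible(x)
}

#' Linear predictor of a Cox fit on new data
#'
#' @param object a `cox_fit`.
#' @param newdata clr matrix; `covariates` as in [fit_cox()] if the model
#'   used them.
#' @param covariates optional covariate matrix aligned with `newdata`.
#' @param ... unused.
#' @return numeric linear predictor (log relative hazard).
#' @export
predict.cox_fit <- function(object, newdata, covariates = NULL, ...) {
  lp <- drop(as.matrix(newdata) %*% object$beta)
  if (!is.null(object$beta_cov)) {
    if (is.null(covariates)) stop("model was fitted with covariates; supply them")
    lp <- lp + drop(as.matrix(covariates) %*% object$beta_cov)
  }
  lp
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the patient with the higher
#' predicted hazard fails first; prediction ties count 1/2. Computed via
#' [survival::concordance()].
#'
#' @param linear_predictor predicted log relative hazard (higher = riskier).
#' @param time,event follow-up and event indicator.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(linear_predictor, time, event) {
  cc <- survival::concordance(survival::Surv(time, as.integer(event)) ~ linear_predictor,
                              reverse = TRUE)
  counts <- cc$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0) {
    stop("no comparable pairs (all observations censored before any event)")
  }
  unname(cc$concordance)
}

#' Median-hazard risk stratification
#'
#' Splits patients into high- and low-risk groups by comparing their linear
#' predictor against the risk threshold frozen at training time (the
#' training-fold median); "high" means strictly above the threshold, so
#' patients exactly at the median fall in the low-risk group.
#'
#' @param fit a `cox_fit`.
#' @param X_test clr matrix of patients to stratify.
#' @param covariates optional covariates (see [fit_cox()]).
#' @param horizon_months display horizon carried to downstream KM analysis
#'   (default 60).
#' @return data frame `sample_id`, `lp`, `group` (`"high"`/`"low"`), with the
#'   horizon in `attr(, "horizon_months")`.
#' @export
stratify_risk <- function(fit, X_test, covariates = NULL,
                          horizon_months = 60) {
  if (!inherits(fit, "cox_fit")) stop("fit must be a fitted cox_fit")
  lp <- predict(fit, X_test, covariates)
  out <- data.frame(
    sample_id = if (!is.null(rownames(X_test))) rownames(X_test)
                else as.character(seq_along(lp)),
    lp = lp,
    group = ifelse(lp > fit$threshold, "high", "low")
  )
  attr(out, "horizon_months") <- horizon_months
  out
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit estimates with log-log 95% confidence bands per group, and
#' the two-sample log-rank chi-square (1 df). Follow-up is truncated at
#' `horizon_months` for display and testing (events beyond the horizon are
#' treated as censored at the horizon).
#'
#' @param groups two-level grouping (e.g. `"high"`/`"low"`).
#' @param time,event follow-up (months) and event indicator.
#' @param horizon_months truncation horizon; `Inf` disables truncation.
#' @return list: `survfit` (curves), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, time, event, horizon_months = 60) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two non-empty groups required")
  event <- as.integer(event)
  t2 <- pmin(time, horizon_months)
  e2 <- as.integer(event == 1L & time <= horizon_months)
  if (sum(e2) == 0L) stop("no events within the horizon; log-rank undefined")
  sf <- survival::survfit(survival::Surv(t2, e2) ~ groups, conf.type = "log-log")
  sd <- survival::survdiff(survival::Surv(t2, e2) ~ groups)
  list(survfit = sf, chisq = unname(sd$chisq), df = 1L,
       p = pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Additive per-HPC decision contributions
#'
#' For a linear Cox model the exact Shapley decomposition of a patient's log
#' relative hazard against a baseline is `beta_i * (x_i - baseline_i)`; the
#' contributions sum to the difference in linear predictors.
#'
#' @param fit a `cox_fit`.
#' @param x one patient's clr vector.
#' @param baseline reference clr vector (typically the cohort mean).
#' @return named contribution vector with the total in `attr(, "total")`.
#' @export
decision_contributions <- function(fit, x, baseline) {
  if (length(x) != length(fit$beta) || length(baseline) != length(fit$beta)) {
    stop("length mismatch with the fitted coefficient vector")
  }
  contrib <- fit$beta * (x - baseline)
  names(contrib) <- paste0("hpc_", seq_along(contrib) - 1L)
  attr(contrib, "total") <- sum(contrib)
  contrib
}

#' Patient-disjoint cross-validated survival prediction
#'
#' Five-fold (by default) cross-validation of the Cox model: per fold, fit on
#' the training patients, evaluate Harrell's C on the held-out patients, and
#' stratify them by the training-fold median linear predictor. The pooled
#' held-out table supports a single KM/log-rank analysis of the median-hazard
#' split.
#'
#' @param X patient clr matrix (one row per patient).
#' @param time,event follow-up and event indicator.
#' @param folds number of folds.
#' @param seed fold-assignment seed (stratified by event status).
#' @param penalty ridge penalty for [fit_cox()].
#' @return list: `per_fold` (fold, c_index), `mean`, `sd`, `held_out`
#'   (pooled data frame with `sample_id`, `fold`, `lp`, `group`, `time`,
#'   `event`).
#' @export
cross_validate_cox <- function(X, time, event, folds = 5L, seed = 1L,
                               penalty = 1e-6) {
  X <- as.matrix(X)
  event <- as.integer(event)
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
  fold <- stratified_folds(ids, event, folds, seed)
  rows <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- fit_cox(X[tr, , drop = FALSE], time[tr], event[tr], penalty = penalty)
    strat <- stratify_risk(fit, X[!tr, , drop = FALSE])
    data.frame(sample_id = ids[!tr], fold = f, lp = strat$lp,
               group = strat$group, time = time[!tr], event = event[!tr],
               c_index = concordance_index(strat$lp, time[!tr], event[!tr]))
  })
  held_out <- do.call(rbind, rows)
  per_fold <- unique(held_out[, c("fold", "c_index")])
  list(per_fold = per_fold, mean = mean(per_fold$c_index),
       sd = sd(per_fold$c_index),
       held_out = held_out[, c("sample_id", "fold", "lp", "group", "time", "event")])
}
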