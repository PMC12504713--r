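#' Binarise mesothelioma subtype labels
#'
#' Pools the sarcomatoid and biphasic subtypes into a single non-epithelioid
#' class (1) against epithelioid (0), the standard prognostic dichotomy.
#'
#' @param records character vector of subtype labels, or a data frame with
#'   columns `patient_id` and `subtype` (then errors name the patient).
#' @return integer vector of 0/1 labels.
#' @export
binarize_subtype <- function(records) {
  if (is.data.frame(records)) {
    labels <- records$subtype
    ids <- records$patient_id
  } else {
    labels <- records
    ids <- seq_along(records)
  }
  bad <- !(labels %in% c("epithelioid", "biphasic", "sarcomatoid"))
  if (any(bad)) {
    stop("unknown subtype '", labels[bad][1], "' for patient ", ids[bad][1])
  }
  as.integer(labels %in% c("biphasic", "sarcomatoid"))
}

#' Edited Nearest Neighbour (ENN) undersampling
#'
#' Removes majority-class samples whose `k` nearest neighbours (Euclidean,
#' among all other samples) disagree with their label by majority vote;
#' minority-class samples are never removed. Intended for training folds
#' only — never resample evaluation data.
#'
#' @param X numeric feature matrix (e.g. clr coordinates).
#' @param y 0/1 labels; both classes must be present.
#' @param k neighbours consulted (default 3).
#' @return list `X`, `y` (reduced), and `removed` (original row indices).
#' @export
enn_undersample <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("ENN requires both classes present")
  counts <- table(y)
  if (counts["0"] == counts["1"]) {
    return(list(X = X, y = y, removed = integer(0)))  # no majority class
  }
  majority <- as.integer(names(counts)[which.max(counts)])
  nn <- knn_index(X, X, k, self_index = seq_len(nrow(X)))
  votes <- matrix(y[nn], nrow(X), k)
  disagree <- rowMeans(votes == y) < 0.5
  removed <- which(disagree & y == majority)
  keep <- setdiff(seq_len(nrow(X)), removed)
  list(X = X[keep, , drop = FALSE], y = y[keep], removed = removed)
}

#' Logistic subtype model on clr compositions
#'
#' Fits two companion models. The predictive model is a ridge-penalised
#' logistic regression on all `c` clr coordinates (tiny penalty, default
#' 1e-6) — the penalty absorbs the exact collinearity of clr coordinates
#' (columns sum to zero) without materially shrinking estimates. The
#' inferential model is an unpenalised ML fit with one reference HPC dropped,
#' providing per-HPC log-odds ratios, Wald 95% confidence intervals and
#' p-values, plus a likelihood-ratio test against the intercept-only model.
#'
#' @param X clr coordinate matrix (samples x HPCs).
#' @param y 0/1 labels (1 = non-epithelioid).
#' @param penalty ridge penalty for the predictive fit.
#' @param reference 1-based column dropped in the inferential fit (default:
#'   the last HPC).
#' @return object of class `subtype_fit`: `b0`, `b1` (length-c predictive
#'   coefficients), `coef_table` (HPC, log-odds, CI, p), `lrt`
#'   (`statistic`, `df`, `p`), `reference`, `separation` flag.
#' @export
fit_subtype <- function(X, y, penalty = 1e-6, reference = ncol(X)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")

  ridge <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = c(100, 1, 0.01) * penalty,
                          standardize = FALSE)
  b <- as.numeric(coef(ridge, s = penalty))

  Xr <- X[, -reference, drop = FALSE]
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ Xr, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  cf <- coef(fit)[-1]                      # NA for aliased (e.g. constant) columns
  est <- unname(cf)
  se <- pv <- rep(NA_real_, length(cf))
  nonalias <- which(!is.na(cf))
  se[nonalias] <- sm[-1, 2]
  pv[nonalias] <- sm[-1, 4]
  hpc_ids <- (seq_len(ncol(X)) - 1L)[-reference]
  if (separation) {
    warning("perfect separation detected; reporting penalised estimates without Wald inference")
    est <- b[-1][-reference]
    se <- rep(NA_real_, length(est))
    pv <- rep(NA_real_, length(est))
  }
  coef_table <- data.frame(
    hpc = hpc_ids, log_odds = unname(est),
    ci_low = unname(est - qnorm(0.975) * se),
    ci_high = unname(est + qnorm(0.975) * se),
    p = unname(pv)
  )
  null_fit <- glm(y ~ 1, family = binomial())
  lrt_stat <- as.numeric(2 * (logLik(fit) - logLik(null_fit)))
  lrt_df <- attr(logLik(fit), "df") - 1L
  structure(list(
    b0 = b[1], b1 = b[-1], coef_table = coef_table,
    lrt = list(statistic = lrt_stat, df = lrt_df,
               p = pchisq(lrt_stat, lrt_df, lower.tail = FALSE)),
    reference = reference, separation = separation, penalty = penalty
  ), class = "subtype_fit")
}

#' @export
predict.subtype_fit <- function(object, newdata, ...) {
  plogis(object$b0 + drop(as.matrix(newdata) %*% object$b1))
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat(sprintf("Logistic subtype model on %d HPCs (reference HPC %d dropped for inference)\n",
              length(x$b1), x$reference - 1L))
  cat(sprintf("LR test: chi-square(%d) = %.2f, p = %.3g\n",
              x$lrt$df, x$lrt$statistic, x$lrt$p))
  invisible(x)
}

#' Patient-disjoint cross-validated subtype classification
#'
#' Stratified k-fold cross-validation in which all rows of a patient fall in
#' the same fold (essential when classifying at slide level with patient
#' labels). ENN undersampling is applied inside each training fold only; test
#' folds are never resampled. Metrics: AUC-ROC, average precision, and
#' sensitivity/specificity at the 0.5 probability threshold.
#'
#' @param X clr coordinate matrix.
#' @param y 0/1 labels.
#' @param patient_ids patient of each row (default: rownames of `X`).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param use_enn apply ENN inside training folds (default TRUE).
#' @param enn_k ENN neighbour count.
#' @param penalty ridge penalty passed to [fit_subtype()].
#' @return list: `per_fold` data frame, `mean`, `sd`, `fold_of_patient`.
#' @export
cross_validate_subtype <- function(X, y, patient_ids = rownames(X),
                                   folds = 5L, seed = 1L, use_enn = TRUE,
                                   enn_k = 3L, penalty = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(nrow(X)))
  pats <- unique(patient_ids)
  pat_label <- vapply(pats, function(p) {
    round(mean(y[patient_ids == p]))
  }, numeric(1))
  if (folds > min(table(pat_label))) stop("fold count exceeds class counts")
  fold_of_patient <- setNames(
    stratified_folds(pats, pat_label, folds, seed), pats)
  fold <- fold_of_patient[patient_ids]

  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    stopifnot(!any(patient_ids[tr] %in% patient_ids[!tr]))  # fold hygiene
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (use_enn) {
      red <- enn_undersample(Xtr, ytr, enn_k)
      Xtr <- red$X; ytr <- red$y
    }
    fit <- fit_subtype(Xtr, ytr, penalty = penalty)
    prob <- predict(fit, X[!tr, , drop = FALSE])
    ss <- sens_spec(prob, y[!tr])
    data.frame(fold = f, auc = auc_score(prob, y[!tr]),
               avg_precision = average_precision(prob, y[!tr]),
               sensitivity = ss["sensitivity"], specificity = ss["specificity"],
               row.names = NULL)
  })
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("auc", "avg_precision", "sensitivity", "specificity")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[metrics]),
       sd = vapply(per_fold[metrics], sd, numeric(1)),
       fold_of_patient = fold_of_patient)
}

#' Principal components of patient clr vectors
#'
#' Centred (unscaled) PCA with a deterministic sign convention: within each
#' component, the loading of largest magnitude is made positive.
#'
#' @param X clr coordinate matrix with at least 3 rows.
#' @param labels optional per-row labels carried into the output for plotting.
#' @return list: `scores` (n x 2 matrix, PC1/PC2), `variance_explained`
#'   (all components), `rotation`, `center`, `labels`.
#' @export
pca_patient_plot <- function(X, labels = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 samples for PCA")
  if (all(abs(scale(X, scale = FALSE)) < 1e-12)) stop("rank-0 input: no variance")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE], variance_explained = ve,
       rotation = pc$rotation, center = pc$center, labels = labels)
}
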