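# Attention-based multiple-instance learning over tile-embedding bags.
#
# Model: per-instance attention score s_k = w' tanh(V h_k) (optionally gated
# by a sigmoid branch: w' [tanh(V h_k) * sigmoid(U h_k)]), attention weights
# a = softmax(s), pooled representation z = sum_k a_k h_k, and a linear
# classifier p = sigmoid(u' z + b) trained with binary cross-entropy.
# Gradients are analytic; optimisation is Adam with one bag per step.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Initialise attention-MIL parameters
#'
#' Weights are drawn from a seeded normal scaled by the inverse square root
#' of the fan-in; biases start at zero.
#'
#' @param dim instance embedding dimensionality.
#' @param hidden_dim attention hidden width (default 64).
#' @param seed RNG seed.
#' @param gated include the sigmoid gate branch.
#' @return parameter list of class `mil_params` (`V`, `w`, `u`, `b`, and `U`
#'   when gated).
#' @export
mil_init <- function(dim, hidden_dim = 64L, seed = 1L, gated = FALSE) {
  stopifnot(hidden_dim >= 1)
  set.seed(sub_seed(seed, "init"))
  p <- list(
    V = matrix(rnorm(hidden_dim * dim, sd = 1 / sqrt(dim)), hidden_dim, dim),
    # w starts at zero so attention is uniform (mean pooling) at first and
    # only sharpens once the classifier has found a useful direction
    w = numeric(hidden_dim),
    u = rnorm(dim, sd = 1 / sqrt(dim)),
    b = 0
  )
  if (gated) {
    p$U <- matrix(rnorm(hidden_dim * dim, sd = 1 / sqrt(dim)), hidden_dim, dim)
  }
  structure(p, class = "mil_params", gated = gated)
}

#' Attention pooling of a bag
#'
#' Computes the attention weights `a_k = softmax_k(w' tanh(V h_k))` and the
#' pooled representation `z = sum_k a_k h_k`. Weights are strictly positive
#' and sum to 1; pooling is invariant to the instance order.
#'
#' @param params a `mil_params` parameter set.
#' @param bag either a bag list with an `instances` matrix or a `K x D`
#'   instance matrix directly.
#' @return list `z` (pooled vector) and `a` (attention weights).
#' @export
attention_pool <- function(params, bag) {
  H <- if (is.list(bag)) bag$instances else bag
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("empty bag")
  if (ncol(H) != ncol(params$V)) stop("instance dimensionality mismatch")
  Th <- tanh(params$V %*% t(H))                    # hidden x K
  G <- if (isTRUE(attr(params, "gated"))) sigmoid(params$U %*% t(H)) else NULL
  A <- if (is.null(G)) Th else Th * G
  s <- drop(crossprod(params$w, A))                # K scores
  a <- softmax(s)
  list(z = drop(crossprod(H, a)), a = a)
}

# Forward pass keeping intermediates for the backward pass.
mil_forward <- function(params, H, gated) {
  Th <- tanh(params$V %*% t(H))
  G <- if (gated) sigmoid(params$U %*% t(H)) else NULL
  A <- if (gated) Th * G else Th
  s <- drop(crossprod(params$w, A))
  a <- softmax(s)
  z <- drop(crossprod(H, a))
  logit <- sum(params$u * z) + params$b
  list(Th = Th, G = G, A = A, s = s, a = a, z = z, logit = logit,
       p = sigmoid(logit))
}

# Analytic gradient of the binary cross-entropy loss for one bag.
mil_gradient <- function(params, H, y, gated) {
  fw <- mil_forward(params, H, gated)
  dlogit <- fw$p - y
  g <- list(u = dlogit * fw$z, b = dlogit)
  dz <- dlogit * params$u                          # D
  da <- drop(H %*% dz)                             # K
  ds <- fw$a * (da - sum(fw$a * da))               # softmax backward
  g$w <- drop(fw$A %*% ds)                         # hidden
  dA <- outer(params$w, ds)                        # hidden x K
  dTh <- if (gated) dA * fw$G else dA
  dpre_tanh <- dTh * (1 - fw$Th^2)
  g$V <- dpre_tanh %*% H
  if (gated) {
    dG <- dA * fw$Th
    dpre_sig <- dG * fw$G * (1 - fw$G)
    g$U <- dpre_sig %*% H
  }
  list(grad = g, loss = -(y * log(fw$p + 1e-12) + (1 - y) * log(1 - fw$p + 1e-12)),
       p = fw$p)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * grads[[nm]]
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * grads[[nm]]^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Fit one attention-MIL model
#'
#' Adam optimisation of the attention pooling and linear classifier with one
#' bag per gradient step; bags are reshuffled every epoch under the seed.
#' When validation bags are supplied, the validation AUC is monitored each
#' epoch and the best-scoring parameters are kept (early stopping after
#' `patience` epochs without improvement).
#'
#' @param bags training bags (see [simulate_bags()] for the structure).
#' @param hidden_dim attention hidden width.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param seed RNG seed (initialisation and shuffling).
#' @param gated use gated attention.
#' @param val_bags optional validation bags for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param restarts maximum random restarts. The loss surface of the small
#'   attention network is non-convex and an occasional initialisation
#'   converges to an attention pattern that ignores the informative tiles
#'   (visible as a training loss stuck far above the successful runs); a
#'   restart with a derived seed is attempted whenever the final training
#'   loss exceeds `restart_loss`, and the run with the best validation AUC
#'   (or, without validation bags, the lowest training loss) is kept.
#' @param restart_loss training-loss level above which a restart is tried.
#' @return object of class `mil_model`: `params`, `gated`, `epochs_run`,
#'   `final_loss`, `restarts_used`.
#' @export
mil_fit <- function(bags, hidden_dim = 64L, lr = 1e-3, epochs = 50L,
                    seed = 1L, gated = FALSE, val_bags = NULL,
                    patience = 10L, restarts = 3L, restart_loss = 0.1) {
  runs <- list()
  for (r in seq_len(max(1L, restarts))) {
    run <- mil_fit_once(bags, hidden_dim, lr, epochs,
                        seed = as.integer((seed + (r - 1L) * 97003) %% 2147483647),
                        gated = gated, val_bags = val_bags,
                        patience = patience)
    runs[[r]] <- run
    if (run$final_loss <= restart_loss) break
  }
  score <- vapply(runs, function(x) {
    if (!is.null(val_bags) && is.finite(x$val_auc)) x$val_auc else -x$final_loss
  }, numeric(1))
  best <- runs[[which.max(score)]]
  best$restarts_used <- length(runs)
  best
}

mil_fit_once <- function(bags, hidden_dim = 64L, lr = 1e-3, epochs = 50L,
                         seed = 1L, gated = FALSE, val_bags = NULL,
                         patience = 10L) {
  if (length(unique(vapply(bags, `[[`, integer(1), "label"))) < 2L) {
    stop("training bags must contain both classes")
  }
  dim <- ncol(bags[[1]]$instances)
  params <- mil_init(dim, hidden_dim, seed, gated)
  state <- adam_state(params)
  set.seed(sub_seed(seed, "shuffle"))
  t <- 0L
  best <- list(auc = -Inf, params = params, since = 0L)
  loss <- NA_real_
  epochs_run <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(bags))
    losses <- numeric(length(bags))
    for (i in seq_along(ord)) {
      bag <- bags[[ord[i]]]
      gr <- mil_gradient(params, bag$instances, bag$label, gated)
      t <- t + 1L
      upd <- adam_step(params, gr$grad, state, lr, t)
      params <- upd$params
      state <- upd$state
      losses[i] <- gr$loss
    }
    loss <- mean(losses)
    epochs_run <- ep
    if (!is.null(val_bags)) {
      val_scores <- vapply(val_bags, function(b) {
        mil_forward(params, b$instances, gated)$p
      }, numeric(1))
      val_auc <- auc_score(val_scores, vapply(val_bags, `[[`, integer(1), "label"))
      if (val_auc > best$auc + 1e-9) {
        best <- list(auc = val_auc, params = params, since = 0L)
      } else {
        # on ties keep the more-trained parameters (the small validation
        # set often saturates long before the model has converged)
        if (val_auc >= best$auc - 1e-9) best$params <- params
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
  }
  if (!is.null(val_bags) && is.finite(best$auc)) params <- best$params
  attr(params, "gated") <- gated
  structure(list(params = params, gated = gated, epochs_run = epochs_run,
                 final_loss = loss,
                 val_auc = if (is.null(val_bags)) NA_real_ else best$auc),
            class = "mil_model")
}

#' Bag-level probability from a trained MIL model
#'
#' @param object a `mil_model`.
#' @param bags a single bag or a list of bags.
#' @param ... unused.
#' @return numeric vector of bag probabilities.
#' @export
predict.mil_model <- function(object, bags, ...) {
  if (!is.null(bags$instances)) bags <- list(bags)
  vapply(bags, function(b) {
    mil_forward(object$params, b$instances, object$gated)$p
  }, numeric(1))
}

#' Cross-validated attention-MIL training
#'
#' Bag-disjoint stratified k-fold cross-validation. Within each fold a
#' fifth of the training bags is held out for early stopping on validation
#' AUC. Reports AUC-ROC, average precision, and sensitivity/specificity at
#' the 0.5 threshold per fold.
#'
#' @param bags labelled bags.
#' @param hidden_dim,lr,epochs,gated,patience training settings (see
#'   [mil_fit()]).
#' @param folds number of folds.
#' @param seed master seed: folds, initialisation and shuffling all derive
#'   from it, so identical seeds give identical metrics.
#' @return list: `per_fold` metrics data frame, `mean`, `sd`, `models`
#'   (per-fold `mil_model`s), `fold` assignment.
#' @export
train_mil <- function(bags, hidden_dim = 64L, lr = 1e-3, epochs = 50L,
                      folds = 5L, seed = 1L, gated = FALSE, patience = 10L) {
  labels <- vapply(bags, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L) stop("bags must contain both classes")
  if (length(bags) < 2L * folds) stop("need at least 2 bags per fold")
  fold <- stratified_folds(seq_along(bags), labels, folds, seed)
  models <- vector("list", folds)
  per_fold <- lapply(seq_len(folds), function(f) {
    tr_idx <- which(fold != f)
    # carve a validation fifth out of the training bags, stratified
    val_sel <- stratified_folds(tr_idx, labels[tr_idx], 5L,
                                sub_seed(seed, "mil") + f) == 1L
    model <- mil_fit(bags[tr_idx[!val_sel]], hidden_dim, lr, epochs,
                     seed = sub_seed(seed, "mil") + f, gated = gated,
                     val_bags = bags[tr_idx[val_sel]], patience = patience)
    models[[f]] <<- model
    te <- which(fold == f)
    prob <- predict(model, bags[te])
    ss <- sens_spec(prob, labels[te])
    data.frame(fold = f, auc = auc_score(prob, labels[te]),
               avg_precision = average_precision(prob, labels[te]),
               sensitivity = ss["sensitivity"], specificity = ss["specificity"],
               row.names = NULL)
  })
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("auc", "avg_precision", "sensitivity", "specificity")
  list(per_fold = per_fold, mean = colMeans(per_fold[metrics]),
       sd = vapply(per_fold[metrics], sd, numeric(1)),
       models = models, fold = fold)
}

#' Attention enrichment on ground-truth signal tiles
#'
#' For positive bags carrying per-tile signal flags (synthetic data only),
#' compares the attention mass placed on signal tiles with the mass a
#' uniform 1/K attention would give them. Values near 1 mean no preference;
#' values above 1 mean the model attends to the informative tiles.
#'
#' @param model a `mil_model`.
#' @param bags bags with logical `signal` flags.
#' @return mean enrichment ratio over positive bags with signal tiles.
#' @export
attention_enrichment <- function(model, bags) {
  pos <- Filter(function(b) b$label == 1L && any(b$signal), bags)
  if (length(pos) == 0L) stop("no positive bags with signal flags")
  ratios <- vapply(pos, function(b) {
    a <- attention_pool(model$params, b)$a
    sum(a[b$signal]) / (sum(b$signal) / length(a))
  }, numeric(1))
  mean(ratios)
}
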