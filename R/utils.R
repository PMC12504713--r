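# Internal helpers shared across modules.

# Named substreams: every stochastic step derives its own seed from the master
# seed so adding a new draw never perturbs the others. Offsets are fixed.
.substream_offsets <- c(
  centroids = 101L, composition = 211L, tiles = 307L, subtype = 401L,
  survival = 503L, censor = 601L, ratings = 701L, bags = 809L,
  signatures = 907L, sampling = 1013L, leiden = 1103L, folds = 1201L,
  mil = 1301L, shuffle = 1409L, init = 1511L
)

sub_seed <- function(seed, purpose) {
  stopifnot(purpose %in% names(.substream_offsets))
  off <- .substream_offsets[[purpose]]
  as.integer((as.numeric(seed) * 2039 + off) %% 2147483647)
}

with_substream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, purpose))
  expr
}

# k nearest neighbours of `query` rows among `ref` rows (Euclidean), computed
# in blocks so the full distance matrix is never materialised. Ties broken
# toward the lower reference row index (order() is stable). Returns an
# n_query x k index matrix; self_index[i] gives the ref row to exclude for
# query i (NA = exclude nothing).
knn_index <- function(query, ref, k, self_index = NULL, block = 1024L) {
  nq <- nrow(query)
  nr <- nrow(ref)
  if (k < 1 || k > nr - !is.null(self_index)) {
    stop("k must be between 1 and the number of available neighbours")
  }
  out <- matrix(0L, nq, k)
  d2out <- matrix(0, nq, k)
  ref_sq <- rowSums(ref^2)
  for (s in seq(1L, nq, block)) {
    e <- min(s + block - 1L, nq)
    idx <- s:e
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), ref_sq, "+") -
      2 * tcrossprod(query[idx, , drop = FALSE], ref)
    for (j in seq_along(idx)) {
      di <- d2[j, ]
      if (!is.null(self_index) && !is.na(self_index[idx[j]])) {
        di[self_index[idx[j]]] <- Inf
      }
      o <- order(di)[seq_len(k)]
      out[idx[j], ] <- o
      d2out[idx[j], ] <- pmax(di[o], 0)
    }
  }
  attr(out, "d2") <- d2out
  out
}

# AUC-ROC with the direction fixed (higher score = class 1), so an inverted
# classifier scores below 0.5 rather than being flipped; ties count 1/2.
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L) || !any(labels == 0L)) stop("AUC needs both classes present")
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

# Average precision: precision averaged at each positive, scores descending,
# ties broken by original index for determinism.
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(-scores, seq_along(scores))
  y <- labels[o]
  if (sum(y) == 0L) stop("average precision needs at least one positive")
  prec <- cumsum(y) / seq_along(y)
  mean(prec[y == 1L])
}

# Sensitivity / specificity of probability scores at a threshold.
sens_spec <- function(prob, labels, threshold = 0.5) {
  pred <- as.integer(prob > threshold)
  labels <- as.integer(labels)
  c(
    sensitivity = if (sum(labels == 1L)) mean(pred[labels == 1L] == 1L) else NA_real_,
    specificity = if (sum(labels == 0L)) mean(pred[labels == 0L] == 0L) else NA_real_
  )
}

# Stratified k-fold assignment over units (e.g. patients). Units of each
# stratum are shuffled under the seed and dealt round-robin, so folds are
# balanced within each class. Returns fold index per unit (1..folds).
stratified_folds <- function(units, strata, folds, seed) {
  stopifnot(length(units) == length(strata), folds >= 2)
  fold <- integer(length(units))
  set.seed(sub_seed(seed, "folds"))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

closure <- function(x) x / sum(x)

# FNV-1a hash of a string, hex encoded; used for config fingerprints in run
# manifests (stable across platforms, no external dependency).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                     # xor touches the low byte only
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 2^32        # exact: product < 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
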