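#' Correlate HPC compositions with signature scores
#'
#' Two-sided Pearson or Spearman correlation between every composition
#' column (clr coordinates or raw proportions, as supplied) and every
#' signature column, on the samples shared by both matrices. Missing
#' signature values are handled pairwise-complete, with the per-pair sample
#' size reported. Constant columns yield an NA coefficient with a warning
#' and are excluded from testing. Spearman p-values are exact (full
#' permutation distribution) for n <= 9 without ties and use the
#' t-approximation otherwise.
#'
#' @param compositions matrix with sample rownames (clr or proportions).
#' @param signatures matrix with sample rownames and named signature columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return data frame of class `association_result`: `feature`, `signature`,
#'   `n`, `estimate`, `p`.
#' @export
correlate <- function(compositions, signatures,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- as.matrix(compositions)
  S <- as.matrix(signatures)
  shared <- intersect(rownames(A), rownames(S))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  A <- A[shared, , drop = FALSE]
  S <- S[shared, , drop = FALSE]
  if (is.null(colnames(A))) colnames(A) <- paste0("hpc_", seq_len(ncol(A)) - 1L)
  n_constant <- 0L
  out <- vector("list", ncol(A) * ncol(S))
  pos <- 0L
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(S))) {
      pos <- pos + 1L
      ok <- complete.cases(A[, i], S[, j])
      x <- A[ok, i]; y <- S[ok, j]
      n <- length(x)
      if (n < 3L || var(x) == 0 || var(y) == 0) {
        n_constant <- n_constant + 1L
        out[[pos]] <- data.frame(feature = colnames(A)[i],
                                 signature = colnames(S)[j], n = n,
                                 estimate = NA_real_, p = NA_real_)
        next
      }
      exact <- method == "spearman" && n <= 9 &&
        !anyDuplicated(x) && !anyDuplicated(y)
      ct <- suppressWarnings(
        cor.test(x, y, method = method, alternative = "two.sided",
                 exact = if (method == "spearman") exact else NULL)
      )
      out[[pos]] <- data.frame(feature = colnames(A)[i],
                               signature = colnames(S)[j], n = n,
                               estimate = unname(ct$estimate),
                               p = ct$p.value)
    }
  }
  if (n_constant > 0L) {
    warning(sprintf("%d pair(s) with a constant or too-short column reported as NA",
                    n_constant))
  }
  res <- do.call(rbind, out)
  class(res) <- c("association_result", "data.frame")
  res
}

#' Retain associations by raw threshold or Benjamini-Hochberg FDR
#'
#' Raw mode keeps tests with `p < alpha` (strict, as in "p-value below
#' 0.01"); BH mode computes step-up adjusted p-values and keeps
#' `p_adj <= alpha`. Adjusted p-values are reported in both modes; NA
#' p-values (degenerate pairs) are never retained and are excluded from the
#' adjustment.
#'
#' @param results an `association_result` (or any data frame with a `p`
#'   column).
#' @param mode `"bh_fdr"` (default) or `"raw_threshold"`.
#' @param alpha significance level in (0, 1); defaults follow common
#'   practice for each mode: 0.05 for BH, 0.01 for the raw threshold.
#' @return the input with `p_adj` and logical `retained` columns appended.
#' @export
filter_and_adjust <- function(results, mode = c("bh_fdr", "raw_threshold"),
                              alpha = NULL) {
  mode <- match.arg(mode)
  if (nrow(results) == 0L) stop("no association results to filter")
  if (is.null(alpha)) alpha <- if (mode == "bh_fdr") 0.05 else 0.01
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ok <- !is.na(results$p)
  results$p_adj <- NA_real_
  results$p_adj[ok] <- p.adjust(results$p[ok], method = "BH")
  results$retained <- if (mode == "bh_fdr") {
    !is.na(results$p_adj) & results$p_adj <= alpha
  } else {
    !is.na(results$p) & results$p < alpha
  }
  results
}
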