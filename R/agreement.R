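#' Majority consensus of multi-rater categorical annotations
#'
#' Summarises an item-by-category count table (e.g. three pathologists
#' assigning each HPC to a morphological category): the modal category per
#' item, a unanimity flag (all raters agree), a complete-disagreement flag
#' (every rater chose a different category), and an unresolved flag for modal
#' ties, for which no consensus is emitted.
#'
#' @param table integer matrix, `n_ij` = raters assigning item i to category
#'   j; every row must sum to the same rater count `n`.
#' @return data frame `item`, `consensus` (category name, NA when tied),
#'   `unanimous`, `complete_disagreement`, `tied`.
#' @export
majority_consensus <- function(table) {
  tab <- validate_rating_table(table)
  n <- sum(tab[1, ])
  cats <- colnames(tab)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    top <- which(row == max(row))
    data.frame(
      item = rownames(tab)[i],
      consensus = if (length(top) == 1L) cats[top] else NA_character_,
      unanimous = max(row) == n,
      complete_disagreement = all(row <= 1L) && sum(row > 0L) == n,
      tied = length(top) > 1L
    )
  })
  do.call(rbind, res)
}

validate_rating_table <- function(table) {
  tab <- as.matrix(table)
  storage.mode(tab) <- "integer"
  if (any(tab < 0L)) stop("rating counts must be non-negative")
  rs <- rowSums(tab)
  if (length(unique(rs)) != 1L) {
    stop("all rows must sum to the same number of raters; ",
         "exclude items with missing raters first")
  }
  if (is.null(rownames(tab))) rownames(tab) <- sprintf("item_%03d", seq_len(nrow(tab)))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("cat_", seq_len(ncol(tab)) - 1L)
  tab
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement for `N` items each rated by the same `n`
#' raters into `k` categories. Category marginals are
#' `p_j = sum_i n_ij / (N n)`; per-item agreement is the fraction of
#' agreeing rater pairs `sum_j n_ij (n_ij - 1) / (n (n - 1))`; the observed
#' agreement `P_bar` is their mean, the chance agreement is
#' `Pe_bar = sum_j p_j^2`, and `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)`.
#' Kappa is 1 for perfect concordance, about 0 for chance-level agreement
#' and negative for worse-than-chance agreement. Because chance agreement
#' depends on the number of available categories, kappa values are not
#' comparable across annotation components with different category sets.
#'
#' @param table item-by-category count matrix; constant row sums `n >= 2`.
#' @return object of class `fleiss_kappa`: `p_j`, `P_bar`, `Pe_bar`,
#'   `kappa`, `n_items`, `n_raters`.
#' @export
fleiss_kappa <- function(table) {
  tab <- validate_rating_table(table)
  n <- sum(tab[1, ])
  N <- nrow(tab)
  if (n < 2L) stop("Fleiss' kappa needs at least 2 raters")
  p_j <- colSums(tab) / (N * n)
  P_i <- rowSums(tab * (tab - 1L)) / (n * (n - 1L))
  P_bar <- mean(P_i)
  Pe_bar <- sum(p_j^2)
  if (1 - Pe_bar < .Machine$double.eps^0.5) {
    stop("all ratings fall in a single category; kappa undefined")
  }
  structure(list(p_j = p_j, P_bar = P_bar, Pe_bar = Pe_bar,
                 kappa = (P_bar - Pe_bar) / (1 - Pe_bar),
                 n_items = N, n_raters = n),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f (N = %d items, n = %d raters; P = %.3f, Pe = %.3f)\n",
              x$kappa, x$n_items, x$n_raters, x$P_bar, x$Pe_bar))
  invisible(x)
}
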