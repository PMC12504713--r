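#' Per-slide or per-patient HPC compositional vectors
#'
#' Converts tile-level HPC assignments into compositional vectors: for each
#' sample, the fraction of its tiles falling in each HPC, a point on the
#' c-part simplex. Patient-level vectors pool raw tile counts across all of a
#' patient's slides (tile-count weighting), not the mean of slide vectors.
#' Slides with fewer than `min_tiles` tiles are dropped before any
#' aggregation, mirroring the usual exclusion of sparsely tiled slides.
#'
#' @param assignment data frame with columns `slide_id`, `hpc` (0-based ids
#'   below `n_clusters`) and, for patient-level grouping, `patient_id`.
#' @param level `"slide"` or `"patient"`.
#' @param n_clusters total number of HPCs `c`; columns are `hpc_0 ... hpc_{c-1}`.
#' @param min_tiles minimum tiles per slide (default 100); slides below it are
#'   excluded with a warning.
#' @param slide_mean if `TRUE`, patient vectors are the unweighted mean of
#'   their slide vectors instead of the tile-pooled frequencies.
#' @return list of class `hpc_composition`: `proportions` (matrix, rows =
#'   samples, rows sum to 1), `n_tiles` (tiles per sample after filtering),
#'   `level`.
#' @export
compute_composition <- function(assignment, level = c("slide", "patient"),
                                n_clusters, min_tiles = 100L,
                                slide_mean = FALSE) {
  level <- match.arg(level)
  if (nrow(assignment) == 0L) stop("empty assignment")
  stopifnot(all(c("slide_id", "hpc") %in% names(assignment)))
  if (any(assignment$hpc < 0L) || any(assignment$hpc >= n_clusters)) {
    stop("HPC ids must lie in [0, n_clusters)")
  }
  slide_n <- table(assignment$slide_id)
  drop <- names(slide_n)[slide_n < min_tiles]
  if (length(drop)) {
    warning(sprintf("dropping %d slide(s) with fewer than %d tiles",
                    length(drop), min_tiles))
    assignment <- assignment[!(assignment$slide_id %in% drop), , drop = FALSE]
    if (nrow(assignment) == 0L) stop("no slides left after min_tiles filter")
  }
  count_matrix <- function(group) {
    ids <- sort(unique(group))
    m <- matrix(0, length(ids), n_clusters,
                dimnames = list(ids, paste0("hpc_", seq_len(n_clusters) - 1L)))
    tab <- table(group, factor(assignment$hpc, levels = 0:(n_clusters - 1L)))
    m[rownames(tab), ] <- as.matrix(tab)
    m
  }
  if (level == "slide") {
    counts <- count_matrix(assignment$slide_id)
  } else {
    stopifnot("patient_id" %in% names(assignment))
    if (slide_mean) {
      sc <- count_matrix(assignment$slide_id)
      sp <- sc / rowSums(sc)
      pat_of_slide <- assignment$patient_id[match(rownames(sc), assignment$slide_id)]
      props <- rowsum(sp, pat_of_slide) / as.vector(table(pat_of_slide)[sort(unique(pat_of_slide))])
      n_tiles <- rowsum(rowSums(sc), pat_of_slide)[, 1]
      out <- list(proportions = props, n_tiles = n_tiles[rownames(props)],
                  level = level)
      class(out) <- "hpc_composition"
      return(out)
    }
    counts <- count_matrix(assignment$patient_id)
  }
  out <- list(proportions = counts / rowSums(counts),
              n_tiles = rowSums(counts), level = level)
  class(out) <- "hpc_composition"
  out
}

#' @export
print.hpc_composition <- function(x, ...) {
  cat(sprintf("HPC compositions: %d %s(s) x %d HPCs (median %d tiles/sample)\n",
              nrow(x$proportions), x$level, ncol(x$proportions),
              as.integer(median(x$n_tiles))))
  invisible(x)
}

#' Presence and prevalence of HPCs across cases
#'
#' An HPC is called "present" in a case when its fraction strictly exceeds
#' `presence_threshold` (default 1%). Prevalence is the fraction of cases in
#' which the HPC is present, banded as rare (< 20%), intermediate (20-80%) or
#' ubiquitous (> 80%).
#'
#' @param compositions an `hpc_composition` or a proportions matrix.
#' @param presence_threshold abundance cut-off in `[0, 1)`; strict inequality.
#' @return data frame `hpc`, `prevalence`, `band`.
#' @export
presence_prevalence <- function(compositions, presence_threshold = 0.01) {
  A <- if (inherits(compositions, "hpc_composition")) compositions$proportions
       else as.matrix(compositions)
  if (nrow(A) < 1L) stop("need at least one composition")
  if (presence_threshold < 0 || presence_threshold >= 1) {
    stop("presence_threshold must lie in [0, 1)")
  }
  prev <- colMeans(A > presence_threshold)
  band <- ifelse(prev < 0.20, "rare", ifelse(prev > 0.80, "ubiquitous",
                                             "intermediate"))
  data.frame(hpc = seq_along(prev) - 1L, prevalence = unname(prev),
             band = unname(band))
}

#' Multiplicative zero replacement on the simplex
#'
#' Replaces zero components by `delta` and rescales the non-zero components by
#' `1 - delta * (number of zeros)`, preserving closure (the result still sums
#' to 1) and the ratios among non-zero parts.
#'
#' @param A composition vector, or matrix with one composition per row.
#' @param delta replacement value; either a scalar or one value per row. Must
#'   satisfy `delta * (#zeros) < 1`. A count-aware default is `0.5 / n_tiles`
#'   (half a tile's worth of frequency), as used by [composition_clr()].
#' @return strictly positive composition(s) of the same shape.
#' @export
multiplicative_replacement <- function(A, delta) {
  vec <- is.null(dim(A))
  A <- rbind(A)
  if (any(A < 0)) stop("compositions must be non-negative")
  if (any(abs(rowSums(A) - 1) > 1e-6)) stop("rows must sum to 1")
  delta <- rep_len(delta, nrow(A))
  if (any(delta <= 0)) stop("delta must be positive")
  nz <- rowSums(A == 0)
  if (any(delta * nz >= 1)) stop("delta too large for the number of zeros")
  out <- A * (1 - delta * nz)
  zero_idx <- which(A == 0, arr.ind = TRUE)
  out[zero_idx] <- delta[zero_idx[, 1]]
  if (vec) drop(out) else out
}

#' Centred log-ratio (clr) transform
#'
#' Maps strictly positive compositions from the c-part simplex to the
#' zero-sum hyperplane of c-dimensional Euclidean space:
#' `clr_i = log(a_i) - mean_j log(a_j)`. Natural logarithm throughout.
#'
#' @param A strictly positive composition vector or matrix (rows =
#'   compositions). Zeros must be replaced first, e.g. with
#'   [multiplicative_replacement()].
#' @return clr coordinates of the same shape; each row sums to 0.
#' @export
clr_transform <- function(A) {
  vec <- is.null(dim(A))
  A <- rbind(A)
  if (any(A <= 0)) stop("clr requires strictly positive entries; replace zeros first")
  l <- log(A)
  out <- l - rowMeans(l)
  if (vec) drop(out) else out
}

#' Compositions to clr coordinates with count-aware zero replacement
#'
#' Convenience wrapper: applies [multiplicative_replacement()] with
#' `delta = 0.5 / n_tiles` per sample (half a tile of pseudo-frequency)
#' followed by [clr_transform()].
#'
#' @param compositions an `hpc_composition` from [compute_composition()], or a
#'   proportions matrix (then `delta` or `n_tiles` must be supplied).
#' @param delta optional explicit replacement value(s), overriding the default.
#' @param n_tiles optional per-sample tile counts used for the default delta.
#' @return clr coordinate matrix, rows named by sample id.
#' @export
composition_clr <- function(compositions, delta = NULL, n_tiles = NULL) {
  if (inherits(compositions, "hpc_composition")) {
    A <- compositions$proportions
    if (is.null(n_tiles)) n_tiles <- compositions$n_tiles
  } else {
    A <- as.matrix(compositions)
  }
  if (is.null(delta)) {
    if (is.null(n_tiles)) stop("supply delta or n_tiles for zero replacement")
    delta <- 0.5 / n_tiles
  }
  clr_transform(multiplicative_replacement(A, delta))
}
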