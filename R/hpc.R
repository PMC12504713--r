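#' Build a k-nearest-neighbour graph over tile embeddings
#'
#' Each tile is linked to its `k` nearest Euclidean neighbours; the directed
#' neighbour lists are mutualised by union, yielding a simple undirected
#' graph. Distance ties are broken toward the lower row index, so the graph
#' is deterministic given the input order.
#'
#' @param vectors embedding matrix, one row per tile; all entries finite.
#' @param k neighbours per tile, `1 <= k < nrow(vectors)`.
#' @return an [igraph::graph] with `nrow(vectors)` vertices.
#' @export
build_knn_graph <- function(vectors, k = 15L) {
  vectors <- as.matrix(vectors)
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  n <- nrow(vectors)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of tiles")
  nbr <- knn_index(vectors, vectors, k, self_index = seq_len(n))
  el <- cbind(rep(seq_len(n), k), as.vector(nbr))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- unique(el)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, t(el))
}

#' Leiden community detection on a neighbour graph
#'
#' Runs the Leiden algorithm (modularity objective) at the given resolution.
#' Communities are relabelled to consecutive 0-based ids ordered by
#' decreasing size (ties toward the community containing the lowest vertex),
#' so labels are stable under the seed.
#'
#' @param graph an igraph graph (e.g. from [build_knn_graph()]).
#' @param resolution Leiden resolution parameter; larger values give more,
#'   smaller communities.
#' @param seed RNG seed for the (stochastic) refinement phase.
#' @param n_iterations Leiden iterations (default 3).
#' @return list: `labels` (0-based integer per vertex), `n_clusters`,
#'   `modularity`, `resolution`.
#' @export
leiden_cluster <- function(graph, resolution = 1, seed = 1L,
                           n_iterations = 3L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  set.seed(sub_seed(seed, "leiden"))
  if (n == 1L) {
    return(list(labels = 0L, n_clusters = 1L, modularity = NA_real_,
                resolution = resolution))
  }
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  raw <- as.integer(igraph::membership(cl))
  sizes <- table(raw)
  first_seen <- tapply(seq_along(raw), raw, min)
  o <- order(-as.integer(sizes), as.integer(first_seen))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[o]] <- seq_along(o) - 1L
  labels <- relabel[raw]
  list(labels = labels, n_clusters = length(sizes),
       modularity = igraph::modularity(graph, raw), resolution = resolution)
}

#' Sweep Leiden resolutions on a fixed graph
#'
#' Clusters the same graph at several resolutions to expose the granularity
#' trade-off; the summary table supports choosing a configuration (e.g. by
#' modularity, or by a target cluster count).
#'
#' @param graph an igraph graph.
#' @param resolutions non-empty numeric vector of resolutions.
#' @param seed RNG seed (shared by all runs).
#' @return list of class `resolution_sweep`: `summary` (data frame
#'   `resolution`, `n_clusters`, `modularity`) and `runs` (per-resolution
#'   [leiden_cluster()] results).
#' @export
sweep_resolutions <- function(graph, resolutions, seed = 1L) {
  if (length(resolutions) == 0L) stop("resolution list must be non-empty")
  runs <- lapply(resolutions, function(r) leiden_cluster(graph, r, seed))
  summary <- data.frame(
    resolution = resolutions,
    n_clusters = vapply(runs, `[[`, integer(1), "n_clusters"),
    modularity = vapply(runs, `[[`, numeric(1), "modularity")
  )
  structure(list(summary = summary, runs = runs), class = "resolution_sweep")
}

#' Select a resolution from a sweep
#'
#' With `target_clusters` given, picks the resolution whose cluster count is
#' closest to the target; otherwise picks the highest-modularity run. Ties go
#' to the smaller resolution.
#'
#' @param sweep a [sweep_resolutions()] result.
#' @param target_clusters optional desired number of clusters.
#' @return the index of the selected run within the sweep.
#' @export
select_resolution <- function(sweep, target_clusters = NULL) {
  s <- sweep$summary
  score <- if (is.null(target_clusters)) -s$modularity
           else abs(s$n_clusters - target_clusters)
  order(score, s$resolution)[1]
}

#' Discover histomorphological phenotype clusters from a tile table
#'
#' The full discovery step: subsample reference tiles (uniformly within each
#' slide, so large slides do not dominate), build the kNN graph, run a Leiden
#' resolution sweep, select a configuration, and package everything needed to
#' assign new tiles into an `hpc_model`.
#'
#' @param tiles tile table with `tile_id`, `slide_id` and embedding columns
#'   `e0, e1, ...` (as written by [simulate_cohort()]).
#' @param subsample number of reference tiles (default 50000); capped at the
#'   number of tiles available.
#' @param k kNN graph degree (default 15).
#' @param resolutions resolution sweep (default `c(0.5, 1, 1.5, 2)`).
#' @param target_clusters optional cluster-count target for
#'   [select_resolution()]; by default the highest-modularity run is kept.
#' @param seed RNG seed covering subsampling and Leiden.
#' @return object of class `hpc_model`: `resolution`, `n_clusters`, `knn_k`,
#'   `reference_ids`, `reference_labels` (0-based), `reference_vectors`,
#'   `sweep` summary and `seed`.
#' @export
fit_hpc_model <- function(tiles, subsample = 50000L, k = 15L,
                          resolutions = c(0.5, 1, 1.5, 2),
                          target_clusters = NULL, seed = 1L) {
  emb_cols <- grep("^e[0-9]+$", names(tiles), value = TRUE)
  if (length(emb_cols) == 0L) stop("no embedding columns (e0, e1, ...) found")
  n <- nrow(tiles)
  take <- min(subsample, n)
  idx <- with_substream(seed, "sampling", {
    slides <- split(seq_len(n), tiles$slide_id)
    quota <- ceiling(take / length(slides))
    picked <- unlist(lapply(slides, function(ix) {
      if (length(ix) <= quota) ix else ix[sample.int(length(ix), quota)]
    }), use.names = FALSE)
    if (length(picked) > take) picked <- sort(picked[sample.int(length(picked), take)])
    sort(picked)
  })
  ref <- as.matrix(tiles[idx, emb_cols, drop = FALSE])
  graph <- build_knn_graph(ref, k)
  sweep <- sweep_resolutions(graph, resolutions, seed)
  best <- select_resolution(sweep, target_clusters)
  run <- sweep$runs[[best]]
  structure(list(
    resolution = run$resolution, n_clusters = run$n_clusters, knn_k = k,
    reference_ids = tiles$tile_id[idx], reference_labels = run$labels,
    reference_vectors = ref, sweep = sweep$summary, seed = seed
  ), class = "hpc_model")
}

#' @export
print.hpc_model <- function(x, ...) {
  cat(sprintf("HPC model: %d clusters at Leiden resolution %g (%d reference tiles, k = %d)\n",
              x$n_clusters, x$resolution, length(x$reference_labels), x$knn_k))
  invisible(x)
}

#' Assign tiles to discovered HPCs
#'
#' Each tile takes the majority HPC label among its `m` nearest reference
#' tiles (Euclidean); ties are broken toward the smaller HPC id. A tile that
#' exactly coincides with a reference tile receives that reference's stored
#' label, so reference tiles always map to themselves. The `"centroid"`
#' method assigns by nearest cluster centroid instead.
#'
#' @param model an `hpc_model` from [fit_hpc_model()].
#' @param vectors embedding matrix of tiles to assign (rownames, if present,
#'   name the result).
#' @param m reference neighbours for the majority vote (default 25).
#' @param method `"knn"` (majority vote, default) or `"centroid"`.
#' @return 0-based integer HPC labels, one per input row.
#' @export
assign_remaining <- function(model, vectors, m = 25L,
                             method = c("knn", "centroid")) {
  method <- match.arg(method)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != ncol(model$reference_vectors)) {
    stop("embedding dimensionality does not match the model")
  }
  if (method == "centroid") {
    cent <- rowsum(model$reference_vectors, model$reference_labels)
    cent <- cent / as.vector(table(model$reference_labels))
    nn <- knn_index(vectors, cent, 1L)
    labels <- as.integer(rownames(cent))[nn[, 1]]
  } else {
    m <- min(m, nrow(model$reference_vectors))
    nn <- knn_index(vectors, model$reference_vectors, m)
    d2 <- attr(nn, "d2")
    scale2 <- 1 + rowSums(vectors^2)
    labels <- vapply(seq_len(nrow(vectors)), function(i) {
      labs <- model$reference_labels[nn[i, ]]
      if (d2[i, 1] <= 1e-7 * scale2[i]) return(labs[1])  # exact duplicate
      votes <- table(labs)
      top <- names(votes)[votes == max(votes)]
      min(as.integer(top))
    }, integer(1))
  }
  names(labels) <- rownames(vectors)
  labels
}

#' Agreement between two clusterings (adjusted Rand index)
#'
#' Convenience wrapper around [mclust::adjustedRandIndex()] for comparing a
#' clustering against planted ground truth.
#'
#' @param labels,truth two label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions, 0 = chance).
#' @export
cluster_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  mclust::adjustedRandIndex(labels, truth)
}
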