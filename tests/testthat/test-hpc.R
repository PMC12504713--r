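test_that("forced nearest neighbours on collinear points", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  g <- build_knn_graph(x, k = 1)
  edges <- igraph::as_edgelist(g)
  edges <- edges[order(edges[, 1]), , drop = FALSE]
  expect_equal(edges, matrix(c(1, 2, 2, 3), 2, 2, byrow = TRUE))
})

test_that("kNN edges match a brute-force distance computation", {
  set.seed(42)
  x <- matrix(rnorm(60 * 5), 60, 5)
  k <- 4
  g <- build_knn_graph(x, k)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  expected <- unique(do.call(rbind, lapply(1:60, function(i) {
    nb <- order(d[i, ])[1:k]
    cbind(pmin(i, nb), pmax(i, nb))
  })))
  got <- igraph::as_edgelist(g)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(got), key(expected))
})

test_that("duplicate points break ties to the lower index without self-loops", {
  x <- matrix(c(0, 0, 0, 5), ncol = 1)
  g <- build_knn_graph(x, k = 1)
  expect_true(igraph::is_simple(g))
  edges <- igraph::as_edgelist(g)
  # points 1-3 are identical: each picks the lowest-index other duplicate
  expect_true(all(c(1, 2) %in% edges[edges[, 2] == 2 | edges[, 1] == 1]))
  expect_error(build_knn_graph(matrix(c(1, NA), 2, 1), 1), "finite")
  expect_error(build_knn_graph(x, k = 4), "k must")
})

test_that("well-separated clusters split the graph into components", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40 * 3, sd = 0.1), 40, 3),
             matrix(rnorm(40 * 3, sd = 0.1) + 50, 40, 3))
  g <- build_knn_graph(x, k = 3)
  expect_gte(igraph::count_components(g), 2)
})

test_that("leiden separates disconnected cliques and handles singletons", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(5))
  for (res in c(0.3, 1)) {
    out <- leiden_cluster(g, resolution = res, seed = 1)
    expect_equal(out$n_clusters, 2)
    expect_equal(length(unique(out$labels[1:6])), 1)
    expect_equal(length(unique(out$labels[7:11])), 1)
  }
  # at high resolution cliques may split, but never merge across components
  hi <- leiden_cluster(g, resolution = 2, seed = 1)
  expect_length(intersect(hi$labels[1:6], hi$labels[7:11]), 0)
  single <- leiden_cluster(igraph::make_empty_graph(1, directed = FALSE), 1, 1)
  expect_equal(single$labels, 0L)
  expect_equal(single$n_clusters, 1L)
  expect_error(leiden_cluster(igraph::make_empty_graph(0, directed = FALSE), 1),
               "empty")
  expect_identical(leiden_cluster(g, 1, seed = 7)$labels,
                   leiden_cluster(g, 1, seed = 7)$labels)
})

test_that("labels are consecutive 0-based and ordered by cluster size", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60 * 4, sd = 0.2), 60, 4),
             matrix(rnorm(20 * 4, sd = 0.2) + 30, 20, 4))
  out <- leiden_cluster(build_knn_graph(x, 5), 1, seed = 1)
  expect_equal(sort(unique(out$labels)), 0:(out$n_clusters - 1))
  # cluster 0 is the bigger one
  expect_gt(sum(out$labels == 0), sum(out$labels == 1))
})

test_that("resolution sweep reports counts and matches single runs", {
  set.seed(3)
  x <- matrix(rnorm(80 * 4), 80, 4)
  g <- build_knn_graph(x, 5)
  sw <- sweep_resolutions(g, 0.8, seed = 2)
  expect_identical(sw$runs[[1]]$labels, leiden_cluster(g, 0.8, seed = 2)$labels)
  expect_error(sweep_resolutions(g, numeric(0)), "non-empty")

  # three disconnected cliques bound the count below at any resolution
  g3 <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(5),
                               igraph::make_full_graph(5))
  sw3 <- sweep_resolutions(g3, c(0.2, 0.5, 1, 2, 4), seed = 1)
  expect_true(all(sw3$summary$n_clusters >= 3))
})

test_that("cluster counts grow with resolution on a seeded graph", {
  sim <- small_cohort(seed = 21, n_patients = 8)
  emb <- as.matrix(sim$tiles[grep("^e[0-9]+$", names(sim$tiles))])
  g <- build_knn_graph(emb[1:600, ], 10)
  sw <- sweep_resolutions(g, c(0.25, 0.5, 1, 2, 4, 8), seed = 5)
  expect_true(all(diff(sw$summary$n_clusters) >= 0))
})

test_that("planted mixture is recovered and held-out tiles assigned", {
  sim <- simulate_cohort(synthetic_config(
    seed = 17, n_patients = 10, n_components = 5, dim = 16,
    slides_per_patient = c(1, 1), tiles_per_slide = c(300, 300),
    component_separation = 8))
  model <- fit_hpc_model(sim$tiles, subsample = 1200, k = 10, seed = 2)
  truth_ref <- sim$truth$tile_component[model$reference_ids]
  expect_gte(cluster_agreement(model$reference_labels, truth_ref), 0.9)

  # self-consistency: reference vectors reproduce reference labels
  self <- assign_remaining(model, model$reference_vectors)
  expect_equal(unname(self), model$reference_labels)

  # held-out tiles get the modal HPC of their planted component
  held <- setdiff(sim$tiles$tile_id, model$reference_ids)
  emb <- as.matrix(sim$tiles[grep("^e[0-9]+$", names(sim$tiles))])
  rownames(emb) <- sim$tiles$tile_id
  assigned <- assign_remaining(model, emb[held, ])
  modal <- tapply(model$reference_labels, truth_ref,
                  function(l) as.integer(names(which.max(table(l)))))
  expect_gte(mean(assigned == modal[as.character(sim$truth$tile_component[held])]),
             0.95)
})

test_that("assignment majority vote follows centroids and breaks ties low", {
  set.seed(4)
  ref <- rbind(matrix(rnorm(30 * 3, sd = 0.05), 30, 3),
               matrix(rnorm(30 * 3, sd = 0.05) + 10, 30, 3))
  model <- structure(list(
    reference_vectors = ref, reference_labels = rep(c(4L, 1L), each = 30),
    n_clusters = 5L, knn_k = 5L, resolution = 1
  ), class = "hpc_model")
  # a point at the centroid of the "4" cloud
  expect_equal(unname(assign_remaining(model, matrix(0, 1, 3), m = 5)), 4L)
  expect_equal(unname(assign_remaining(model, matrix(10, 1, 3), m = 5)), 1L)
  # equidistant vote split 2/2 goes to the smaller HPC id
  refs <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2)
  model2 <- structure(list(reference_vectors = refs,
                           reference_labels = c(3L, 3L, 0L, 0L)),
                      class = "hpc_model")
  expect_equal(unname(assign_remaining(model2, matrix(0.5, 1, 2), m = 4)), 0L)
  expect_error(assign_remaining(model2, matrix(0, 1, 5)), "dimensionality")
})

test_that("centroid assignment agrees with the vote on clean clusters", {
  sim <- simulate_cohort(synthetic_config(
    seed = 19, n_patients = 6, n_components = 3, dim = 8,
    slides_per_patient = c(1, 1), tiles_per_slide = c(200, 200),
    component_separation = 10))
  model <- fit_hpc_model(sim$tiles, subsample = 500, k = 8, seed = 3,
                         target_clusters = 3)
  emb <- as.matrix(sim$tiles[grep("^e[0-9]+$", names(sim$tiles))][1:100, ])
  expect_equal(assign_remaining(model, emb, method = "centroid"),
               assign_remaining(model, emb, method = "knn"))
})
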