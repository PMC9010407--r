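test_that("PCA reproduces exact low-rank structure and orders components", {
  withr::with_seed(1, {
    basis <- matrix(rnorm(2 * 8), 2, 8)
    scores <- matrix(rnorm(30 * 2), 30, 2)
    x <- scores %*% basis  # exact rank 2
  })
  m <- AnnotatedMatrix(x)
  m <- reduce_pca(m, reduction_params(n_components = 2, seed = 0))
  emb <- m$embeddings[["reduced"]]
  ev <- attr(emb, "explained_variance")
  expect_true(all(diff(ev) <= 1e-8))  # non-increasing
  # rank-2 data reconstructs exactly from 2 components
  centred <- sweep(x, 2, colMeans(x))
  recon_var <- sum(ev) / (sum(centred^2) / (nrow(x) - 1))
  expect_equal(recon_var, 1, tolerance = 1e-8)
  expect_error(reduce_pca(m, reduction_params(n_components = 50)),
               "admissible maximum")
})

test_that("PCA of collinear 2-D points matches the analytic direction", {
  # three collinear points along (3, 1): the lone principal axis is
  # (3, 1)/sqrt(10), up to sign
  x <- rbind(c(0, 0), c(3, 1), c(6, 2))
  m <- reduce_pca(AnnotatedMatrix(x), reduction_params(n_components = 1))
  emb <- m$embeddings[["reduced"]]
  expected <- sweep(x, 2, colMeans(x)) %*% (c(3, 1) / sqrt(10))
  expect_true(max(abs(emb - expected)) < 1e-10 ||
              max(abs(emb + expected)) < 1e-10)
})

test_that("UMAP produces requested dimensions deterministically", {
  withr::with_seed(2, x <- matrix(rnorm(60 * 19), 60, 19))
  m <- AnnotatedMatrix(x)
  m2 <- reduce_umap(m, n_dims = 2, seed = 9)
  expect_equal(dim(m2$embeddings[["umap"]]), c(60L, 2L))
  m10 <- reduce_umap(m, n_dims = 10, seed = 9, key = "umap10")
  expect_equal(dim(m10$embeddings[["umap10"]]), c(60L, 10L))
  m2b <- reduce_umap(m, n_dims = 2, seed = 9)
  expect_identical(m2$embeddings[["umap"]], m2b$embeddings[["umap"]])
  tiny <- AnnotatedMatrix(matrix(rnorm(10), 5, 2))
  expect_error(reduce_umap(tiny, n_dims = 2, n_neighbors = 15),
               "n_neighbors")
})

test_that("kNN graph matches brute force and symmetrizes by union", {
  # three exactly equidistant points (unit basis vectors in 3-D), k = 1:
  # every tie resolves to the lowest index, so nodes 2 and 3 both pick
  # node 1, node 1 picks node 2, and the union is {1-2, 1-3}; degree >= k
  # holds for every node after symmetrization
  eq <- diag(3)
  g <- build_knn_graph(eq, k = 1)
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(1L, 3L)))
  expect_true(all(tabulate(c(g$edges), nbins = 3) >= 1))

  # two well-separated blobs: no cross-blob edges, verified by brute force
  withr::with_seed(4, {
    blob1 <- matrix(rnorm(10 * 3), 10, 3)
    blob2 <- matrix(rnorm(10 * 3) + 50, 10, 3)
  })
  g2 <- build_knn_graph(rbind(blob1, blob2), k = 3)
  cross <- xor(g2$edges[, 1] <= 10, g2$edges[, 2] <= 10)
  expect_false(any(cross))
  # brute-force oracle: recompute directed lists from the distance matrix
  d <- as.matrix(dist(rbind(blob1, blob2)))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[1:3])  # 3 x 20, column per node
  expected <- unique(t(apply(cbind(rep(1:20, each = 3), as.vector(nn)),
                             1, sort)))
  got <- g2$edges[order(g2$edges[, 1], g2$edges[, 2]), ]
  expected <- expected[order(expected[, 1], expected[, 2]), ]
  expect_equal(unname(got), unname(expected))

  # k = n - 1 gives the complete graph
  g3 <- build_knn_graph(matrix(rnorm(12), 6, 2), k = 5)
  expect_equal(nrow(g3$edges), choose(6, 2))
  expect_error(build_knn_graph(matrix(0, 3, 2), k = 3), "smaller")
})

test_that("leiden separates components and keeps cliques whole", {
  p <- leiden(graph_two_triangles(), cluster_params(seed = 1))
  expect_equal(length(unique(p$labels)), 2L)
  expect_equal(p$labels[1:3], rep(p$labels[1], 3))
  expect_equal(p$labels[4:6], rep(p$labels[4], 3))
  expect_equal(partition_quality(graph_two_triangles(), p, 1), 0.5)

  k5 <- leiden(graph_complete(5), cluster_params(seed = 1))
  expect_equal(length(unique(k5$labels)), 1L)

  # never worse than the all-singleton partition
  g <- graph_erdos(8, 0.5, seed = 3)
  lp <- leiden(g, cluster_params(seed = 2))
  singletons <- partition(0:7)
  expect_gte(partition_quality(g, lp, 1),
             partition_quality(g, singletons, 1))
  expect_error(leiden(neighbor_graph(0, matrix(integer(0), ncol = 2))),
               "empty")
})

test_that("leiden quality agrees with igraph's on the same partitions", {
  skip_if_not_installed("igraph")
  for (g in list(graph_two_triangles(), graph_barbell(),
                 graph_erdos(8, 0.5, 11))) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    for (res in c(0.5, 1, 2)) {
      p <- leiden(g, cluster_params(resolution = res, seed = 1))
      q_ig <- igraph::modularity(ig, p$labels + 1, resolution = res)
      expect_equal(partition_quality(g, p, res), q_ig, tolerance = 1e-12)
      # and our optimum is at least as good as igraph's own Leiden run
      cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                                   resolution = res, n_iterations = 5)
      expect_gte(partition_quality(g, p, res) + 1e-9,
                 igraph::modularity(ig, igraph::membership(cl),
                                    resolution = res))
    }
  }
})

test_that("resolution drives granularity from one cluster to singletons", {
  g <- graph_erdos(10, 0.5, seed = 21)
  k_hi <- length(unique(leiden(g, cluster_params(resolution = 100,
                                                 seed = 1))$labels))
  k_lo <- length(unique(leiden(g, cluster_params(resolution = 1e-4,
                                                 seed = 1))$labels))
  expect_gt(k_hi, k_lo)
  expect_equal(k_lo, 1L)
})

test_that("frozen cells obey co-membership and separation exactly", {
  # all cells frozen: output equals the init up to relabelling
  g <- graph_barbell()
  init <- partition(c(0, 0, 0, 1, 1, 1), rep(TRUE, 6))
  out <- leiden_semisupervised(g, init, cluster_params(seed = 1))
  expect_equal(ari(out, init), 1)

  # no cells frozen: behaves like unconstrained leiden (same quality)
  init2 <- partition(c(0, 1, 0, 1, 0, 1))
  out2 <- leiden_semisupervised(g, init2, cluster_params(seed = 1))
  un <- leiden(g, cluster_params(seed = 1))
  expect_equal(partition_quality(g, out2, 1), partition_quality(g, un, 1))

  # a wrong member left unfrozen moves back to its own triangle
  init3 <- partition(c(0, 0, 0, 0, 1, 1),
                     c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  out3 <- leiden_semisupervised(g, init3, cluster_params(seed = 1))
  expect_equal(out3$labels[4], out3$labels[5])
  expect_equal(length(unique(out3$labels[1:3])), 1L)
  expect_false(out3$labels[1] == out3$labels[4])
  # and this matches the constrained exhaustive optimum
  best <- best_partition_exhaustive(g, 1, init3)
  expect_equal(partition_quality(g, out3, 1), best$quality)

  expect_error(leiden_semisupervised(g, partition(c(0, 1), c(TRUE, TRUE)),
                                     cluster_params()), "covers")
})

test_that("constrained runs satisfy the frozen-pair conditions on random cases", {
  for (s in 1:10) {
    g <- graph_erdos(6 + (s %% 3), 0.5, seed = 200 + s)
    init <- random_constrained_init(g, seed = 300 + s)
    out <- leiden_semisupervised(g, init, cluster_params(seed = s))
    expect_true(frozen_pairs_consistent(init, out))
  }
})

test_that("ari matches its closed form and an independent implementation", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(3, 3, 7, 7)), 1)  # relabelling
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(ari(c(0, 1), c(0, 1, 2)), "lengths")
  skip_if_not_installed("mclust")
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- sample(0:3, 40, replace = TRUE)
      b <- sample(0:3, 40, replace = TRUE)
      expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
})
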