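test_that("knn graph includes each vertex's top-k neighbours, symmetrized", {
  ## 3-sample worked case: nearest-neighbour edges only
  s <- similarity_matrix(matrix(c(1, .9, .2, .9, 1, .8, .2, .8, 1), 3))
  g <- build_knn_graph(s, 1)
  A <- as.matrix(g$adjacency)
  expect_equal(A[1, 2], 0.9)
  expect_equal(A[2, 3], 0.8)
  expect_equal(A[1, 3], 0)

  ## k = n - 1 gives the complete graph
  sim <- random_similarity(8, seed = 3)
  g <- build_knn_graph(sim, 7)
  expect_equal(Matrix::nnzero(g$adjacency), 8 * 7)

  expect_error(build_knn_graph(sim, 0), "k_neighbors")
  expect_error(build_knn_graph(sim, 8), "k_neighbors")
})

test_that("knn edge set equals a per-row sort oracle on random matrices", {
  for (seed in 1:5) {
    sim <- random_similarity(12, seed = seed)
    g <- build_knn_graph(sim, 3)
    A <- as.matrix(g$adjacency)
    mine <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
    want <- oracle_knn_edges(unclass(sim), 3)
    expect_equal(mine[order(mine[, 1], mine[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    ## weights are the similarities
    expect_equal(A[mine], unclass(sim)[mine])
  }
})

test_that("graph partitioning handles degenerate requests", {
  sim <- random_similarity(10, seed = 9)
  g <- build_knn_graph(sim, 3)
  expect_equal(unname(partition_graph(g, 1)), rep(1L, 10))
  expect_error(partition_graph(g, 0), "a must be")
  expect_error(partition_graph(g, 11), "a must be")
  ## a = n: every vertex its own sub-partition
  expect_equal(sort(unname(partition_graph(g, 10))), 1:10)
})

test_that("two connected components split with zero cut", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 0.9
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 0.8
  W <- pmax(W, t(W))
  g <- neighbor_graph(as_sparse_general(W), k_neighbors = 2)
  lab <- partition_graph(g, 2)
  expect_true(same_partition(lab, c(1, 1, 1, 2, 2, 2)))
})

test_that("bisection cut weight matches the exhaustive oracle (<=12 vertices)", {
  set.seed(101)
  matches <- 0L
  trials <- 60L
  for (t in seq_len(trials)) {
    n <- sample(6:12, 1)
    W <- random_graph_matrix(n)
    minside <- max(1, ceiling(0.025 * n))
    bb <- chamclust:::best_bisection(as_sparse_general(W), seq_len(n), 0.025)
    opt <- oracle_min_bisection(W, minside)
    expect_lte(bb$cut, 1.05 * opt + 1e-9)
    if (abs(bb$cut - opt) < 1e-9) matches <- matches + 1L
  }
  expect_gte(matches, 0.9 * trials)
})

test_that("agglomeration merges the strongest-linked pair first", {
  ## two sub-partitions joined at 0.9, third attached at 0.1
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[3, 4] <- W[5, 6] <- 0.95   # intra sub-partition edges
  W[2, 3] <- 0.9                          # sub-partition 1 -- 2
  W[4, 5] <- 0.1                          # sub-partition 2 -- 3
  W <- pmax(W, t(W))
  g <- neighbor_graph(as_sparse_general(W), k_neighbors = 1)
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L)
  out <- agglomerate_subpartitions(g, labels, 2, linkage = "single")
  expect_true(same_partition(out, c(1, 1, 1, 1, 2, 2)))

  ## k_final = current count leaves labels unchanged
  same <- agglomerate_subpartitions(g, labels, 3, linkage = "single")
  expect_equal(unname(as.integer(same)), labels)
  expect_error(agglomerate_subpartitions(g, labels, 4), "exceeds")
})

test_that("singleton agglomeration reproduces textbook linkage sequences", {
  for (seed in 1:6) {
    sim <- random_similarity(10, seed = 200 + seed)
    g <- build_knn_graph(sim, 9)        # complete graph
    for (lk in c("single", "complete")) {
      lab <- agglomerate_subpartitions(g, 1:10, 1, linkage = lk)
      hist <- attr(lab, "merge_history")
      hc <- stats::hclust(stats::as.dist(1 - unclass(sim)), method = lk)
      for (step in 1:9) {
        mine <- partition_after(hist, 10, step)
        want <- stats::cutree(hc, k = 10 - step)
        expect_true(same_partition(mine, want),
                    info = sprintf("seed %d %s step %d", seed, lk, step))
      }
    }
  }
})

test_that("chameleon recovers separated blobs and validates parameters", {
  d <- simulate_gaussian_clusters(
    centroids = list(c(0, 0), c(10, 0), c(0, 10)),
    sizes = c(25, 30, 20), sd = 1, seed = 4)
  sim <- points_to_similarity(d$points)
  sol <- chameleon_cluster(sim, k_neighbors = 10, k_final = 3)
  expect_equal(ari(sol$labels, d$labels), 1)
  expect_identical(sol$params$algorithm, "chameleon")

  ## a = k_final = n: all singletons
  small <- random_similarity(6, seed = 12)
  singl <- chameleon_cluster(small, k_neighbors = 2, k_final = 6, a = 6)
  expect_equal(sort(singl$labels), 1:6)

  expect_error(chameleon_cluster(small, 2, k_final = 4, a = 2), ">=")
})

test_that("chameleon is reproducible given identical inputs", {
  sim <- random_similarity(40, seed = 77)
  s1 <- chameleon_cluster(sim, k_neighbors = 5, k_final = 4, a = 8,
                          linkage = "complete", seed = 1)
  s2 <- chameleon_cluster(sim, k_neighbors = 5, k_final = 4, a = 8,
                          linkage = "complete", seed = 1)
  expect_identical(s1$labels, s2$labels)
})

test_that("deep sub-partitioning with single linkage induces chaining", {
  ## on gradient-structured (continuum) data, agglomerating many
  ## sub-partitions with single linkage concentrates samples in one big
  ## cluster: the largest/median size ratio grows versus a = k
  for (s in 1:3) {
    cm <- simulate_community_matrix(n_clusters = 6, plots_per_cluster = 50,
                                    pool_size = 25, p_in = 0.6,
                                    p_out = 0.04, n_shared = 10,
                                    gradient_strength = 0.8, seed = s)
    sim <- bray_curtis_similarity(cm$matrix)
    g <- build_knn_graph(sim, 15)
    ratio <- vapply(c(6L, 60L), function(a) {
      lab <- partition_graph(g, a, prioritize_large = TRUE)
      if (a > 6) lab <- agglomerate_subpartitions(g, lab, 6,
                                                  linkage = "single")
      sz <- table(lab)
      max(sz) / stats::median(sz)
    }, numeric(1))
    expect_gt(ratio[2], ratio[1])
  }
})
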