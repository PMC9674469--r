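test_that("kmeans on coincident points gives a perfect zero-WCSS split", {
  pts <- rbind(matrix(0, 3, 2), matrix(10, 3, 2))
  rownames(pts) <- paste0("s", 1:6)
  sol <- kmeans_points(pts, 2, seed = 1, n_restarts = 5)
  expect_true(same_partition(sol$labels, rep(1:2, each = 3)))
  expect_equal(sol$params$wcss, 0)
})

test_that("kmeans achieves the enumerated optimum on a 6-point case", {
  set.seed(31)
  pts <- matrix(stats::rnorm(12), 6, 2)
  sol <- kmeans_points(pts, 2, seed = 2, n_restarts = 25)
  ## enumerate all 2^5 - 1 bipartitions
  best <- Inf
  for (mask in 1:31) {
    side <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(side) || all(side)) next
    w <- 0
    for (part in list(pts[side, , drop = FALSE], pts[!side, , drop = FALSE]))
      w <- w + sum(scale(part, scale = FALSE)^2)
    best <- min(best, w)
  }
  expect_equal(sol$params$wcss, best, tolerance = 1e-8)
})

test_that("kmedoids recovers identity blocks and the k = 1 medoid", {
  s <- matrix(0, 6, 6)
  s[1:3, 1:3] <- 1
  s[4:6, 4:6] <- 1
  sim <- similarity_matrix(s)
  sol <- kmedoids_dissimilarity(sim, 2, seed = 1)
  expect_true(same_partition(sol$labels, rep(1:2, each = 3)))

  sim1 <- random_similarity(8, seed = 41)
  one <- kmedoids_dissimilarity(sim1, 1, seed = 1)
  expect_equal(unname(one$labels), rep(1L, 8))
  ## objective for k = 1 is the best total similarity to a single medoid
  expect_equal(one$params$objective, max(colSums(unclass(sim1))))
})

test_that("kmedoids objective beats a randomized assignment search", {
  sim <- random_similarity(8, seed = 55)
  sol <- kmedoids_dissimilarity(sim, 2, seed = 3, n_restarts = 10)
  set.seed(77)
  rand_best <- -Inf
  for (r in 1:200) {
    med <- sort(sample(8, 2))
    assign <- apply(unclass(sim)[, med], 1, which.max)
    assign[med] <- 1:2
    obj <- sum(unclass(sim)[cbind(1:8, med[assign])])
    rand_best <- max(rand_best, obj)
  }
  expect_gte(sol$params$objective, rand_best - 1e-9)
})

test_that("flexible UPGMA follows the Lance-Williams recurrence exactly", {
  ## first merge is the closest pair
  s3 <- similarity_matrix(matrix(c(1, .9, .2, .9, 1, .3, .2, .3, 1), 3))
  sol3 <- flexible_upgma(s3, 2)
  expect_true(same_partition(sol3$labels, c(1, 1, 2)))

  ## full merge sequence vs the hand-executed recurrence, beta in {0, -0.25}
  for (beta in c(0, -0.25)) {
    sim <- random_similarity(6, seed = 83)
    sol <- flexible_upgma(sim, 1, beta = beta)
    hist <- attr(sol, "merge_history")
    want <- oracle_lw_flexible(1 - unclass(sim), beta, steps = 5)
    for (st in 1:5) {
      expect_equal(hist[[st]]$height, want[[st]]$height, tolerance = 1e-12)
      expect_setequal(hist[[st]]$a, want[[st]]$a)
      expect_setequal(hist[[st]]$b, want[[st]]$b)
    }
  }

  ## beta = 0 with size weighting is plain UPGMA: same partitions as hclust
  sim <- random_similarity(12, seed = 91)
  hc <- stats::hclust(stats::as.dist(1 - unclass(sim)), method = "average")
  for (k in c(2, 4, 6)) {
    mine <- flexible_upgma(sim, k, beta = 0)
    expect_true(same_partition(mine$labels, stats::cutree(hc, k)))
  }

  expect_equal(sort(unname(flexible_upgma(sim, 12)$labels)), 1:12)
  expect_error(flexible_upgma(sim, 2, beta = 1), "beta")
})

test_that("merge heights are monotone for beta <= 0", {
  for (seed in 1:5) {
    sim <- random_similarity(15, seed = 300 + seed)
    for (beta in c(0, -0.1, -0.5)) {
      h <- attr(flexible_upgma(sim, 1, beta = beta), "heights")
      expect_true(all(diff(h) >= -1e-12),
                  info = sprintf("seed %d beta %.1f", seed, beta))
    }
  }
})

test_that("polythetic division recovers tight groups and matches its oracle", {
  ## two tight groups: within-d 0.05, between-d 0.9
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.05
  d[4:6, 4:6] <- 0.05
  diag(d) <- 0
  sim <- similarity_matrix(1 - d)
  sol <- polythetic_division(sim, 2)
  expect_true(same_partition(sol$labels, rep(1:2, each = 3)))

  ## k = 1 is the identity
  expect_equal(unname(polythetic_division(sim, 1)$labels), rep(1L, 6))

  ## 7-sample split equals the direct simulation of the splinter rules
  for (seed in 1:5) {
    sim7 <- random_similarity(7, seed = 400 + seed)
    sol7 <- polythetic_division(sim7, 2)
    spl <- oracle_splinter(1 - unclass(sim7), 1:7)
    want <- ifelse(1:7 %in% spl, 2L, 1L)
    expect_true(same_partition(sol7$labels, want), info = seed)
  }
})

test_that("baselines produce exhaustive, exclusive, deterministic labels", {
  sim <- random_similarity(20, seed = 7)
  pts <- matrix(stats::rnorm(40), 20, 2)
  sols <- list(
    kmeans_points(pts, 4, seed = 5),
    kmedoids_dissimilarity(sim, 4, seed = 5),
    flexible_upgma(sim, 4),
    polythetic_division(sim, 4))
  for (sol in sols) {
    expect_length(sol$labels, 20)
    expect_equal(sort(unique(unname(sol$labels))), 1:4,
                 info = sol$params$algorithm)
  }
  expect_identical(kmeans_points(pts, 4, seed = 5)$labels, sols[[1]]$labels)
  expect_identical(kmedoids_dissimilarity(sim, 4, seed = 5)$labels,
                   sols[[2]]$labels)
})
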