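test_that("hypergeometric tails match pmf enumeration and flag correctly", {
  cm <- random_binary_community(20, 12, seed = 3)
  labels <- rep(1:4, each = 5)
  dt <- diagnostic_table(cm, labels)
  for (r in sample(nrow(dt), 40)) {
    expect_equal(dt$hypergeom_p[r],
                 oracle_hyper_tail(dt$x[r], dt$N[r], dt$X[r], dt$m[r]),
                 tolerance = 1e-10)
  }
  expect_identical(dt$diag_hypergeom, dt$hypergeom_p > 0.999)
})

test_that("degenerate species are never concentration-diagnostic", {
  v <- rbind(p1 = c(1, 1, 0), p2 = c(1, 0, 0), p3 = c(1, 0, 1),
             p4 = c(1, 0, 1))
  colnames(v) <- c("everywhere", "only_c1", "only_c2")
  labels <- c(1, 1, 2, 2)
  dt <- diagnostic_table(community_matrix(v), labels)
  ## species present in every plot: x = m always, P(H < m) = 0
  ubiq <- dt[dt$species == "everywhere", ]
  expect_true(all(ubiq$hypergeom_p == 0))
  expect_false(any(ubiq$diag_hypergeom))
  ## species absent from a cluster: P(H < 0) = 0
  absent <- dt[dt$species == "only_c2" & dt$cluster == 1, ]
  expect_equal(absent$hypergeom_p, 0)
})

test_that("phi follows the 2x2 formula and its standardization limit", {
  ## perfect association with equal cluster sizes
  v <- rbind(p1 = c(1, 1), p2 = c(1, 1), p3 = c(0, 1), p4 = c(0, 1))
  colnames(v) <- c("faithful", "shared")
  dt <- diagnostic_table(community_matrix(v), c(1, 1, 2, 2))
  expect_equal(dt$phi[dt$species == "faithful" & dt$cluster == 1], 1)
  ## identical in/out frequency: independence, phi = 0
  expect_equal(dt$phi[dt$species == "shared" & dt$cluster == 1], 0)

  ## N=10, m=5, X=4, x=4 against hand arithmetic (equal sizes: raw = std)
  v2 <- matrix(0, 10, 1, dimnames = list(paste0("p", 1:10), "spA"))
  v2[1:4, 1] <- 1
  v2 <- cbind(v2, filler = 1)  # keep all plots nonempty
  labels <- rep(1:2, each = 5)
  dt2 <- diagnostic_table(community_matrix(v2), labels)
  phi_hand <- (10 * 4 - 5 * 4) / sqrt(5 * 4 * (10 - 5) * (10 - 4))
  expect_equal(dt2$phi[dt2$species == "spA" & dt2$cluster == 1], phi_hand,
               tolerance = 1e-12)
  ## cross-check against the raw (unstandardized) computation
  raw <- diagnostic_table(community_matrix(v2), labels,
                          standardize = FALSE)
  expect_equal(raw$phi[raw$species == "spA" & raw$cluster == 1], phi_hand,
               tolerance = 1e-12)

  ## X = 0 or X = N: phi defined as 0
  expect_equal(dt2$phi[dt2$species == "filler"], c(0, 0))
})

test_that("standardized phi equals raw phi only at equal cluster sizes", {
  cm <- random_binary_community(24, 10, seed = 8)
  even <- rep(1:3, each = 8)
  std <- diagnostic_table(cm, even, standardize = TRUE)
  raw <- diagnostic_table(cm, even, standardize = FALSE)
  expect_equal(std$phi, raw$phi, tolerance = 1e-12)

  uneven <- rep(1:3, c(14, 6, 4))
  std_u <- diagnostic_table(cm, uneven, standardize = TRUE)
  raw_u <- diagnostic_table(cm, uneven, standardize = FALSE)
  expect_gt(max(abs(std_u$phi - raw_u$phi)), 1e-6)
})

test_that("diagnostic counts summarize flags, frequency floor and medians", {
  v <- rbind(p1 = c(1, 1, 0), p2 = c(1, 1, 0), p3 = c(0, 1, 1),
             p4 = c(0, 1, 1), p5 = c(0, 1, 1), p6 = c(0, 1, 0))
  colnames(v) <- c("a", "b", "c")
  dt <- diagnostic_table(community_matrix(v), c(1, 1, 2, 2, 2, 2))
  counts <- diagnostic_counts(dt, freq_threshold = 0.3)
  expect_true(counts$n_phi >= counts$n_phi_freq)
  expect_true(counts$n_hypergeom >= counts$n_hypergeom_freq)

  ## no passers: totals 0 and medians absent
  flat <- dt
  flat$diag_hypergeom <- FALSE
  flat$diag_phi <- FALSE
  empty <- diagnostic_counts(flat)
  expect_equal(empty$n_hypergeom, 0)
  expect_true(is.na(empty$median_freq_hypergeom))

  ## single passer: count 1, median = its frequency
  one <- flat
  one$diag_phi[3] <- TRUE
  one$in_cluster_frequency[3] <- 0.5
  oc <- diagnostic_counts(one)
  expect_equal(oc$n_phi_freq, 1)
  expect_equal(oc$median_freq_phi, 0.5)
})

test_that("planted faithful species are recovered by both criteria", {
  cm <- simulate_community_matrix(n_clusters = 4, plots_per_cluster = 25,
                                  pool_size = 12, p_in = 0.9, p_out = 0.02,
                                  n_shared = 6, seed = 5)
  dt <- diagnostic_table(cm$matrix, cm$labels)
  hits <- vapply(seq_along(cm$planted_diagnostics), function(c) {
    sp <- cm$planted_diagnostics[[c]]
    rows <- dt[dt$cluster == c & dt$species %in% sp, ]
    mean(rows$diag_hypergeom & rows$diag_phi)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("reference confusion is the shared-species proportion", {
  dt <- data.frame(
    species = c("s1", "s2", "s3", "s4", "s5"),
    cluster = c(1, 1, 1, 2, 2),
    diag_hypergeom = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    diag_phi = FALSE)
  ref <- structure(list(A = c("s1", "s2", "s3", "s9"),
                        B = c("s4", "s5"),
                        C = c("s7", "s8")),
                   class = "reference_classification")
  conf <- reference_confusion(dt, ref)
  expect_equal(conf["A", "1"], 0.75)   # 3 of 4 class species diagnostic
  expect_equal(conf["B", "2"], 0.5)    # s4 diagnostic, s5 not flagged
  expect_equal(conf["C", "1"], 0)      # disjoint
  expect_equal(rownames(conf), c("A", "B", "C"))
})
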