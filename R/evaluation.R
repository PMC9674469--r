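#' Nearest-neighbour misplacement rate
#'
#' The proportion of samples located in clusters other than that of their
#' nearest neighbour: for each sample the most similar other sample(s) are
#' found, and the sample counts as misplaced iff no tied nearest neighbour
#' shares its cluster (ties are resolved in the sample's favour, so only
#' unambiguous violations are penalized).
#'
#' @param sim a [similarity_matrix()].
#' @param labels cluster labels (vector or [cluster_solution()]).
#' @return Fraction in \[0, 1\].
#' @export
misplacement_rate <- function(sim, labels) {
  sim <- as_similarity(sim)
  labels <- solution_labels(labels)
  n <- nrow(sim)
  if (n < 2) stop("misplacement needs at least two samples", call. = FALSE)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  misplaced <- vapply(seq_len(n), function(i) {
    s <- sim[i, ]
    s[i] <- -Inf
    nn <- which(s == max(s))
    !any(labels[nn] == labels[i])
  }, logical(1))
  mean(misplaced)
}

#' Within-cluster homogeneity
#'
#' Average pairwise within-cluster similarity.  By default the mean is
#' pooled over all unordered within-cluster pairs across clusters; with
#' `pooled = FALSE` a mean of per-cluster means is returned instead.
#' Singleton clusters contribute no pairs; if every cluster is a singleton
#' the quantity is undefined and an error is raised.
#'
#' @param sim a [similarity_matrix()].
#' @param labels cluster labels (vector or [cluster_solution()]).
#' @param pooled pool pairs across clusters (default) or average per-cluster
#'   means.
#' @return Mean similarity in \[0, 1\].
#' @export
homogeneity <- function(sim, labels, pooled = TRUE) {
  sim <- as_similarity(sim)
  labels <- solution_labels(labels)
  per <- lapply(unique(labels), function(c) {
    members <- which(labels == c)
    if (length(members) < 2) return(NULL)
    block <- sim[members, members, drop = FALSE]
    block[upper.tri(block)]
  })
  per <- Filter(Negate(is.null), per)
  if (!length(per))
    stop("all clusters are singletons: homogeneity undefined", call. = FALSE)
  if (pooled) mean(unlist(per)) else mean(vapply(per, mean, numeric(1)))
}

#' Cluster-size evenness profile
#'
#' Cluster sizes ranked in increasing order, each expressed as a proportion
#' of the largest cluster's size.  A flat profile at 1 indicates equal-size
#' clusters; a profile hugging 0 until the last entry indicates that one
#' cluster holds most samples (the chaining symptom).
#'
#' @param labels cluster labels (vector or [cluster_solution()]).
#' @return Non-decreasing numeric vector ending in 1.
#' @export
evenness_profile <- function(labels) {
  labels <- solution_labels(labels)
  sizes <- sort(as.integer(table(labels)))
  sizes / max(sizes)
}

solution_labels <- function(labels) {
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  as.integer(labels)
}

#' Evaluate one clustering solution
#'
#' @param sim a [similarity_matrix()].
#' @param solution a [cluster_solution()] or label vector.
#' @return A one-row `data.frame` with misplacement rate, homogeneity,
#'   cluster count, largest cluster share and a chaining flag (largest
#'   cluster holding more than half the samples).
#' @export
evaluate_solution <- function(sim, solution) {
  labels <- solution_labels(solution)
  sizes <- as.integer(table(labels))
  hom <- tryCatch(homogeneity(sim, labels), error = function(e) NA_real_)
  data.frame(
    n = length(labels),
    n_clusters = length(sizes),
    misplacement = misplacement_rate(sim, labels),
    homogeneity = hom,
    max_cluster_share = max(sizes) / length(labels),
    chaining_suspect = max(sizes) > 0.5 * length(labels))
}

#' Run a parameter sweep of clustering trials
#'
#' Executes one clustering per row of `grid` and evaluates each solution.
#' Grid columns select the algorithm and its parameters: `algorithm`
#' (`"chameleon"`, `"kmedoids"`, `"upgma"`, `"divisive"`), `k`, and for
#' chameleon `k_neighbors`, `a` (NA = agglomerative phase omitted),
#' `linkage`, `prioritize_large`.  Rows where the largest cluster exceeds
#' half the samples are flagged chaining-suspect.
#'
#' @param sim a [similarity_matrix()].
#' @param grid `data.frame` of trial parameters, one row per trial.
#' @param seed base seed passed to stochastic algorithms (offset by row).
#' @return `data.frame` with one evaluated row per grid point.
#' @export
sweep_trials <- function(sim, grid, seed = 1) {
  if (!is.data.frame(grid) || nrow(grid) == 0)
    stop("grid must be a non-empty data.frame", call. = FALSE)
  if (!"algorithm" %in% names(grid) || !"k" %in% names(grid))
    stop("grid needs at least columns `algorithm` and `k`", call. = FALSE)
  sim <- as_similarity(sim)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- as.list(grid[r, , drop = FALSE])
    sol <- run_trial(sim, p, seed = seed + r - 1L)
    cbind(grid[r, , drop = FALSE], evaluate_solution(sim, sol),
          row.names = NULL)
  })
  do.call(rbind, rows)
}

run_trial <- function(sim, p, seed) {
  algo <- as.character(p$algorithm)
  k <- as.integer(p$k)
  na_null <- function(x) if (is.null(x) || is.na(x)) NULL else x
  or_default <- function(x, default) na_null(x) %||% default
  switch(algo,
    chameleon = chameleon_cluster(
      sim, k_neighbors = as.integer(or_default(p$k_neighbors, 15L)),
      k_final = k, a = na_null(p$a),
      linkage = as.character(or_default(p$linkage, "complete")),
      prioritize_large = isTRUE(p$prioritize_large), seed = seed),
    kmedoids = kmedoids_dissimilarity(sim, k, seed = seed),
    upgma = flexible_upgma(sim, k,
                           beta = as.numeric(or_default(p$beta, -0.1))),
    divisive = polythetic_division(sim, k),
    stop("unknown algorithm: ", algo, call. = FALSE))
}
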