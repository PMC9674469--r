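#' k-means clustering of coordinate data
#'
#' Lloyd iteration from `k` distinct data points sampled at random, best of
#' `n_restarts` restarts by total within-cluster sum of squares.  Used for
#' point-cloud data (e.g. the simulated bivariate-normal clusters); for
#' community data on a similarity matrix see [kmedoids_dissimilarity()].
#'
#' @param points numeric n x d coordinate matrix.
#' @param k number of clusters (<= number of distinct points).
#' @param seed integer seed for centroid sampling.
#' @param n_restarts number of random restarts.
#' @return A [cluster_solution()]; `params$wcss` holds the achieved total
#'   within-cluster sum of squares.
#' @export
kmeans_points <- function(points, k, seed = 1, n_restarts = 25) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  uniq <- unique(points)
  if (k > nrow(uniq))
    stop("k exceeds the number of distinct points", call. = FALSE)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
      fit <- suppressWarnings(tryCatch(
        stats::kmeans(points, centers = centers, iter.max = 200,
                      algorithm = "Lloyd"),
        error = function(e) NULL))
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best))
    stop("k-means failed to produce k nonempty clusters", call. = FALSE)
  cluster_solution(
    stats::setNames(normalize_labels(best$cluster), rownames(points)),
    params = list(algorithm = "kmeans", k = k, seed = seed,
                  n_restarts = n_restarts, wcss = best$tot.withinss))
}

#' k-medoids clustering on a similarity matrix
#'
#' PAM-style alternation on precomputed similarities: seed `k` distinct
#' medoids at random, assign every sample to its most similar medoid, then
#' update each medoid to the member maximizing total within-cluster
#' similarity; repeat to convergence.  Best of `n_restarts` restarts by the
#' total within-cluster similarity objective.  This is the nonhierarchical
#' allocation baseline for community data.
#'
#' @param sim a [similarity_matrix()].
#' @param k number of clusters.
#' @param seed integer seed for medoid sampling.
#' @param n_restarts number of random restarts.
#' @return A [cluster_solution()]; `params$objective` holds the summed
#'   similarity of samples to their medoids.
#' @export
kmedoids_dissimilarity <- function(sim, k, seed = 1, n_restarts = 10) {
  sim <- as_similarity(sim)
  n <- nrow(sim)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  best_obj <- -Inf; best_lab <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      medoids <- sort(sample.int(n, k))
      for (it in seq_len(100)) {
        ## assignment: most similar medoid, ties to the lowest medoid index
        smat <- sim[, medoids, drop = FALSE]
        assign <- max.col(smat, ties.method = "first")
        assign[medoids] <- seq_len(k)      # a medoid stays in its own cluster
        new_med <- vapply(seq_len(k), function(c) {
          members <- which(assign == c)
          tot <- colSums(sim[members, members, drop = FALSE])
          members[which.max(tot)]
        }, integer(1))
        new_med <- sort(new_med)
        if (identical(new_med, medoids)) break
        medoids <- new_med
      }
      smat <- sim[, medoids, drop = FALSE]
      assign <- max.col(smat, ties.method = "first")
      assign[medoids] <- seq_len(k)
      obj <- sum(smat[cbind(seq_len(n), assign)])
      if (obj > best_obj + 1e-12) { best_obj <- obj; best_lab <- assign }
    }
  })
  cluster_solution(
    stats::setNames(normalize_labels(best_lab), rownames(sim)),
    params = list(algorithm = "kmedoids", k = k, seed = seed,
                  n_restarts = n_restarts, objective = best_obj))
}

## Lance-Williams flexible-beta agglomeration with group-size (arithmetic
## mean) weighting: d(k, i+j) = ai*d(k,i) + aj*d(k,j) + beta*d(i,j) with
## ai = (1 - beta) * ni / (ni + nj).  Returns the merge sequence and heights.
lw_flexible_merge <- function(diss, beta) {
  n <- nrow(diss)
  d <- diss
  diag(d) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)                  # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  groups <- lapply(seq_len(n), identity)
  history <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    flat <- which.min(d)               # ties -> lowest linear index
    j <- (flat - 1L) %/% n + 1L
    i <- (flat - 1L) %% n + 1L
    lo <- min(i, j); hi <- max(i, j)
    h <- d[lo, hi]
    height[step] <- h
    merge[step, ] <- sort(c(node[lo], node[hi]))
    history[[step]] <- list(a = groups[[lo]], b = groups[[hi]], height = h)
    ai <- (1 - beta) * sizes[lo] / (sizes[lo] + sizes[hi])
    aj <- (1 - beta) * sizes[hi] / (sizes[lo] + sizes[hi])
    newd <- ai * d[lo, ] + aj * d[hi, ] + beta * h
    newd[!active] <- Inf
    d[lo, ] <- newd
    d[, lo] <- newd
    d[lo, lo] <- Inf
    active[hi] <- FALSE
    d[hi, ] <- Inf
    d[, hi] <- Inf
    sizes[lo] <- sizes[lo] + sizes[hi]
    groups[[lo]] <- c(groups[[lo]], groups[[hi]])
    node[lo] <- step
  }
  list(merge = merge, height = height, history = history)
}

#' Flexible-beta group-average hierarchical clustering
#'
#' Agglomerative clustering on dissimilarity `1 - s` using Lance-Williams
#' flexible-beta updates with arithmetic (group-size-weighted) averaging:
#' `d(k, ij) = ai d(k,i) + aj d(k,j) + beta d(i,j)` with
#' `ai = (1 - beta) ni / (ni + nj)`.  `beta = 0` reduces to plain UPGMA
#' group averaging.  The dendrogram is cut at `k` clusters.
#'
#' @param sim a [similarity_matrix()].
#' @param k number of clusters.
#' @param beta mixing parameter in (-1, 1); ecological practice commonly
#'   uses a small negative value (default -0.1).
#' @return A [cluster_solution()]; attribute `merge_history` holds the full
#'   merge sequence with heights.
#' @export
flexible_upgma <- function(sim, k, beta = -0.1) {
  sim <- as_similarity(sim)
  if (beta <= -1 || beta >= 1)
    stop("beta must lie strictly between -1 and 1", call. = FALSE)
  n <- nrow(sim)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  fit <- lw_flexible_merge(1 - unclass(sim), beta)
  memb <- seq_len(n)
  if (k < n) for (step in seq_len(n - k)) {
    h <- fit$history[[step]]
    memb[c(h$a, h$b)] <- min(memb[c(h$a, h$b)])
  }
  sol <- cluster_solution(
    stats::setNames(normalize_labels(memb), rownames(sim)),
    params = list(algorithm = "upgma", k = k, beta = beta))
  attr(sol, "merge_history") <- fit$history
  attr(sol, "heights") <- fit$height
  sol
}

#' Polythetic divisive clustering (splinter-group method)
#'
#' Iterative division on dissimilarity `1 - s`: until `k` clusters exist,
#' the cluster with the highest mean within-cluster dissimilarity (or the
#' largest diameter, if `select = "diameter"`) is divided.  A splinter group
#' is seeded with the member of maximal mean dissimilarity to its fellows;
#' then the member whose mean dissimilarity to the remainder exceeds its
#' mean dissimilarity to the splinter by the largest positive margin is
#' moved, repeatedly, until no positive candidate remains.
#'
#' @param sim a [similarity_matrix()].
#' @param k number of clusters.
#' @param select rule for choosing the cluster to divide: highest mean
#'   within-cluster dissimilarity (`"mean"`, default) or largest diameter
#'   (`"diameter"`).
#' @return A [cluster_solution()].
#' @export
polythetic_division <- function(sim, k, select = c("mean", "diameter")) {
  select <- match.arg(select)
  sim <- as_similarity(sim)
  n <- nrow(sim)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  d <- 1 - unclass(sim)
  memb <- rep(1L, n)
  while (max(memb) < k) {
    crit <- vapply(seq_len(max(memb)), function(c) {
      members <- which(memb == c)
      if (length(members) < 2) return(-Inf)
      dm <- d[members, members, drop = FALSE]
      if (select == "mean") mean(dm[upper.tri(dm)]) else max(dm)
    }, numeric(1))
    target <- which.max(crit)          # ties -> lowest cluster index
    members <- which(memb == target)
    split <- splinter_division(d, members)
    memb[split$splinter] <- max(memb) + 1L
    memb <- normalize_labels(memb)
  }
  cluster_solution(
    stats::setNames(memb, rownames(sim)),
    params = list(algorithm = "divisive", k = k, select = select))
}

## one splinter division of `members` given the full dissimilarity matrix
splinter_division <- function(d, members) {
  dm <- d[members, members, drop = FALSE]
  m <- length(members)
  mean_to_rest <- rowSums(dm) / (m - 1)
  seed <- which.max(mean_to_rest)      # ties -> lowest index
  in_splinter <- rep(FALSE, m)
  in_splinter[seed] <- TRUE
  repeat {
    nr <- sum(!in_splinter); ns <- sum(in_splinter)
    if (nr <= 1) break
    to_spl <- rowSums(dm[, in_splinter, drop = FALSE]) / ns
    to_rem <- rowSums(dm[, !in_splinter, drop = FALSE]) / pmax(nr - 1, 1)
    gain <- ifelse(in_splinter, -Inf, to_rem - to_spl)
    v <- which.max(gain)
    if (gain[v] <= 0) break
    in_splinter[v] <- TRUE
  }
  list(splinter = members[in_splinter], remainder = members[!in_splinter])
}
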