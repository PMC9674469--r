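#' Simulate Gaussian point clusters with uneven sizes
#'
#' Draws each cluster's points as its centroid plus isotropic bivariate
#' normal noise.  Two presets reproduce the classic demonstration of
#' central-tendency clustering failing on clusters of very uneven density:
#' six clusters with sizes 30, 50, 500, 50, 70, 300 (`"uneven_a"`) or
#' 20, 100, 500, 20, 100, 500 (`"uneven_b"`), sd = 1, with default
#' centroids placed so that every pair is at least 6 sd apart and each dense
#' cluster has a sparse cluster adjacent to it.
#'
#' @param preset `"uneven_a"`, `"uneven_b"`, or `NULL` to supply
#'   `centroids` and `sizes` directly.
#' @param centroids list of 2-D centroid coordinates (one per cluster).
#' @param sizes integer sample count per cluster.
#' @param sd standard deviation of the isotropic noise (default 1).
#' @param seed integer seed.
#' @return List with `points` (n x 2 matrix, rows named `s1..sn`) and
#'   `labels` (true cluster index per point).
#' @export
simulate_gaussian_clusters <- function(preset = NULL, centroids = NULL,
                                       sizes = NULL, sd = 1, seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("uneven_a", "uneven_b"))
    centroids <- default_centroids()
    sizes <- switch(preset,
                    uneven_a = c(30, 50, 500, 50, 70, 300),
                    uneven_b = c(20, 100, 500, 20, 100, 500))
  }
  if (is.null(centroids) || is.null(sizes))
    stop("supply a preset or both centroids and sizes", call. = FALSE)
  if (length(centroids) != length(sizes))
    stop("centroids and sizes must have equal length", call. = FALSE)
  if (any(sizes < 1)) stop("cluster sizes must be >= 1", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  n <- sum(sizes)
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_along(sizes), function(c) {
      cbind(stats::rnorm(sizes[c], centroids[[c]][1], sd),
            stats::rnorm(sizes[c], centroids[[c]][2], sd))
    }))
  })
  rownames(pts) <- paste0("s", seq_len(n))
  list(points = pts, labels = rep(seq_along(sizes), sizes))
}

## six centroids, minimum pairwise distance 6: each dense cluster (3rd and
## 6th in the presets) has a sparse neighbour at exactly distance 6
default_centroids <- function() {
  list(c(6, 0),    # A: sparse, adjacent to C
       c(0, 6),    # B
       c(0, 0),    # C: dense
       c(18, 6),   # D: sparse, adjacent to F
       c(12, 0),   # E
       c(12, 6))   # F: dense
}

#' Convert point coordinates to a similarity matrix
#'
#' Default transformation: `s(i, j) = 1 - d(i, j) / max(d)` with Euclidean
#' distances, so the two most distant points have similarity 0.  The
#' alternative `method = "gaussian"` uses the kernel
#' `exp(-d^2 / (2 bandwidth^2))` (bandwidth defaults to the median pairwise
#' distance).
#'
#' @param points numeric n x d coordinate matrix.
#' @param method `"linear"` (default) or `"gaussian"`.
#' @param bandwidth kernel bandwidth for `method = "gaussian"`.
#' @return A [similarity_matrix()].
#' @export
points_to_similarity <- function(points, method = c("linear", "gaussian"),
                                 bandwidth = NULL) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least two points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  if (method == "linear") {
    mx <- max(d)
    if (mx == 0) {
      warning("all points identical; similarities all 1")
      s <- matrix(1, nrow(d), ncol(d))
    } else s <- 1 - d / mx
  } else {
    bw <- bandwidth %||% stats::median(d[upper.tri(d)])
    if (bw <= 0) bw <- 1
    s <- exp(-d^2 / (2 * bw^2))
  }
  dimnames(s) <- list(rownames(points), rownames(points))
  similarity_matrix(s)
}

#' Simulate a presence-absence community matrix with cluster structure
#'
#' Each cluster has a private pool of `pool_size` species occurring in its
#' own plots with probability `p_in` and elsewhere with probability `p_out`;
#' `n_shared` additional species occur everywhere with `p_in`.  With
#' `gradient_strength > 0` the private species respond to a latent 1-D
#' gradient instead of a block structure: plots are positioned along the
#' gradient (clusters occupy consecutive segments), each private species is
#' given an optimum within its cluster's segment, and its occurrence
#' probability decays as a Gaussian of the plot-optimum distance with width
#' `gradient_strength` (in units of one cluster segment).  Larger values
#' spread species across adjacent clusters, producing the chained, elongated
#' similarity structure of a compositional continuum.
#'
#' Empty plots are redrawn (up to 100 attempts each); the generator is a
#' pure function of its parameters and `seed`.
#'
#' @param n_clusters number of clusters.
#' @param plots_per_cluster plots per cluster (scalar or vector; may be
#'   uneven).
#' @param pool_size private species per cluster.
#' @param p_in within-cluster occurrence probability.
#' @param p_out cross-cluster occurrence probability (< `p_in`).
#' @param n_shared species occurring everywhere with `p_in`.
#' @param gradient_strength 0 for discrete clusters (default), > 0 for
#'   gradient-driven turnover.
#' @param seed integer seed.
#' @return List with `matrix` (binary [community_matrix()]), `labels`
#'   (true cluster per plot) and `planted_diagnostics` (list cluster ->
#'   private species ids).
#' @export
simulate_community_matrix <- function(n_clusters = 5,
                                      plots_per_cluster = 30,
                                      pool_size = 20, p_in = 0.9,
                                      p_out = 0.02, n_shared = 10,
                                      gradient_strength = 0, seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (p_in <= p_out)
    stop("p_in must exceed p_out for recoverable structure", call. = FALSE)
  if (length(plots_per_cluster) == 1)
    plots_per_cluster <- rep(plots_per_cluster, n_clusters)
  stopifnot(length(plots_per_cluster) == n_clusters)
  n <- sum(plots_per_cluster)
  labels <- rep(seq_len(n_clusters), plots_per_cluster)
  species <- c(
    unlist(lapply(seq_len(n_clusters), function(c)
      paste0("c", c, "_sp", seq_len(pool_size)))),
    if (n_shared > 0) paste0("shared_sp", seq_len(n_shared)))
  sp_cluster <- c(rep(seq_len(n_clusters), each = pool_size),
                  rep(0L, n_shared))  # 0 = shared
  if (p_in == 0 && p_out == 0)
    stop("all occurrence probabilities are zero", call. = FALSE)
  ## plot positions / species optima on a latent gradient in [0, n_clusters]
  pos <- unlist(lapply(seq_len(n_clusters), function(c)
    c - 1 + (seq_len(plots_per_cluster[c]) - 0.5) / plots_per_cluster[c]))
  withr::with_seed(seed, {
    opt <- ifelse(sp_cluster == 0, NA,
                  sp_cluster - 1 + stats::runif(length(species)))
    prob <- matrix(p_out, n, length(species))
    for (s in seq_along(species)) {
      if (sp_cluster[s] == 0L) {
        prob[, s] <- p_in
      } else if (gradient_strength > 0) {
        f <- exp(-((pos - opt[s]) / gradient_strength)^2 / 2)
        prob[, s] <- p_out + (p_in - p_out) * f
      } else {
        prob[labels == sp_cluster[s], s] <- p_in
      }
    }
    vals <- matrix(stats::rbinom(length(prob), 1, prob), n)
    for (i in which(rowSums(vals) == 0)) {
      for (attempt in seq_len(100)) {
        vals[i, ] <- stats::rbinom(ncol(vals), 1, prob[i, ])
        if (sum(vals[i, ]) > 0) break
      }
      if (sum(vals[i, ]) == 0)
        stop("could not draw a nonempty plot in 100 attempts",
             call. = FALSE)
    }
  })
  dimnames(vals) <- list(paste0("p", seq_len(n)), species)
  planted <- split(species[sp_cluster > 0], sp_cluster[sp_cluster > 0])
  names(planted) <- paste0("cluster_", names(planted))
  list(matrix = community_matrix(vals), labels = labels,
       planted_diagnostics = planted)
}
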