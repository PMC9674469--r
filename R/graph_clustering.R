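#' Build a k-nearest-neighbour similarity graph
#'
#' Each sample is linked to its `k_neighbors` most similar other samples;
#' ties at the k-th rank are all included (avoids order dependence).  The
#' directed neighbour lists are union-symmetrized: an edge is kept if either
#' endpoint selected the other.  Edge weight equals the pairwise similarity.
#'
#' @param sim a [similarity_matrix()] (or coercible symmetric matrix).
#' @param k_neighbors neighbourhood size, between 1 and n - 1.
#' @return A [neighbor_graph()].
#' @export
build_knn_graph <- function(sim, k_neighbors) {
  sim <- as_similarity(sim)
  n <- nrow(sim)
  k_neighbors <- as.integer(k_neighbors)
  if (is.na(k_neighbors) || k_neighbors < 1 || k_neighbors > n - 1)
    stop(sprintf("k_neighbors must be in [1, %d]", n - 1), call. = FALSE)
  kth <- vapply(seq_len(n), function(i) {
    s <- sim[i, ]
    s[i] <- -Inf
    -sort(-s, partial = k_neighbors)[k_neighbors]
  }, numeric(1))
  sel <- unclass(sim) >= matrix(kth, n, n)   # row i: s(i, .) >= kth(i)
  diag(sel) <- FALSE
  sel <- sel | t(sel)                        # union symmetrization
  adj <- methods::as(methods::as(
    Matrix::Matrix(unclass(sim) * sel, sparse = TRUE), "generalMatrix"),
    "CsparseMatrix")
  neighbor_graph(adj, k_neighbors, sample_ids = rownames(sim))
}

## --- internal: sparse-column access and connected components -------------

col_nonzero <- function(W, v) {
  p <- W@p
  r <- seq.int(p[v] + 1L, p[v + 1L], length.out = p[v + 1L] - p[v])
  list(i = W@i[r] + 1L, x = W@x[r])
}

components_of <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- col_nonzero(W, v)$i
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

## --- internal: Fiduccia-Mattheyses style refinement ----------------------

## side: logical vector (TRUE = side 1).  minside: minimum vertices per
## side.  W may be a dense base matrix or a dgCMatrix; deg = rowSums(W).
fm_refine <- function(W, deg, side, minside, max_passes = 8L) {
  dense <- is.matrix(W)
  n <- length(side)
  conn1 <- if (dense) as.vector(W %*% side)
           else as.vector(W %*% as.numeric(side))
  cut <- sum((deg - conn1)[side])
  for (pass in seq_len(max_passes)) {
    cur <- side
    c1 <- conn1
    n1 <- sum(cur); n2 <- n - n1
    ## gain of moving v = conn to other side - conn to own side
    ##   = sign(v) * (deg - 2 * conn_to_side1), sign = +1 on side 1
    sgn <- 2 * cur - 1
    gv <- sgn * (deg - 2 * c1)
    movable <- rep(TRUE, n)
    curcut <- cut
    bestcut <- cut
    beststep <- 0L
    moves <- integer(n)
    nmoves <- 0L
    gv[!movable] <- -Inf              # locked vertices never selected
    repeat {
      if (n1 > minside && n2 > minside) {
        v <- which.max(gv)            # ties -> lowest index
        g <- gv[v]
      } else {
        cand <- gv
        if (n1 <= minside) cand[cur] <- -Inf
        if (n2 <= minside) cand[!cur] <- -Inf
        v <- which.max(cand)
        g <- cand[v]
      }
      if (g == -Inf) break
      from1 <- cur[v]
      cur[v] <- !from1
      sgn[v] <- -sgn[v]
      if (from1) { n1 <- n1 - 1L; n2 <- n2 + 1L }
      else { n1 <- n1 + 1L; n2 <- n2 - 1L }
      movable[v] <- FALSE
      if (dense) {
        c1 <- if (from1) c1 - W[, v] else c1 + W[, v]
        gv <- sgn * (deg - 2 * c1)
        gv[!movable] <- -Inf
      } else {
        cnz <- col_nonzero(W, v)
        nb <- cnz$i
        c1[nb] <- if (from1) c1[nb] - cnz$x else c1[nb] + cnz$x
        upd <- nb[movable[nb]]
        gv[upd] <- sgn[upd] * (deg[upd] - 2 * c1[upd])
        gv[v] <- -Inf
      }
      nmoves <- nmoves + 1L
      moves[nmoves] <- v
      curcut <- curcut - g
      if (curcut < bestcut - 1e-12) { bestcut <- curcut; beststep <- nmoves }
    }
    if (bestcut < cut - 1e-12) {
      flip <- moves[seq_len(beststep)]
      side[flip] <- !side[flip]
      conn1 <- if (dense) as.vector(W %*% side)
               else as.vector(W %*% as.numeric(side))
      cut <- bestcut
    } else break
  }
  side
}

cut_weight <- function(W, side) {
  if (!any(side) || all(side)) return(0)
  sum(W[side, !side, drop = FALSE])
}

cut_edges <- function(W, side) {
  if (!any(side) || all(side)) return(0L)
  blk <- W[side, !side, drop = FALSE]
  if (is.matrix(blk)) sum(blk > 0) else Matrix::nnzero(blk)
}

## incremental sweep over an ordering of vertices: cut of every prefix
prefix_cuts <- function(W, deg, ord) {
  n <- length(ord)
  dense <- is.matrix(W)
  conn <- numeric(n)
  cuts <- numeric(n)
  cut <- 0
  for (p in seq_len(n)) {
    v <- ord[p]
    cut <- cut + deg[v] - 2 * conn[v]
    if (dense) conn <- conn + W[, v] else {
      cnz <- col_nonzero(W, v); conn[cnz$i] <- conn[cnz$i] + cnz$x
    }
    cuts[p] <- cut
  }
  cuts
}

best_prefix_side <- function(W, deg, ord, minside) {
  n <- length(ord)
  cuts <- prefix_cuts(W, deg, ord)
  valid <- seq_len(n - 1)
  valid <- valid[valid >= minside & (n - valid) >= minside]
  if (!length(valid)) return(NULL)
  p <- valid[which.min(cuts[valid])]
  side <- rep(FALSE, n)
  side[ord[seq_len(p)]] <- TRUE
  side
}

## greedy max-connection (Prim-like) growth order from a start vertex
growth_order <- function(W, deg, start) {
  n <- nrow(W)
  dense <- is.matrix(W)
  conn <- numeric(n)
  added <- rep(FALSE, n)
  ord <- integer(n)
  v <- start
  for (p in seq_len(n)) {
    ord[p] <- v
    added[v] <- TRUE
    if (dense) conn <- conn + W[, v] else {
      cnz <- col_nonzero(W, v); conn[cnz$i] <- conn[cnz$i] + cnz$x
    }
    if (p == n) break
    cand <- conn
    cand[added] <- -Inf
    v <- which.max(cand)
  }
  ord
}

## best bisection of the sub-graph induced by `idx`; returns members of the
## two sides, the dissolved (cut) similarity weight and cut edge count
best_bisection <- function(W, idx, balance_floor, spectral_max = 600L) {
  n <- length(idx)
  stopifnot(n >= 2)
  minside <- max(1L, ceiling(balance_floor * n))
  if (2L * minside > n) minside <- n %/% 2L
  Wsub <- W[idx, idx, drop = FALSE]
  ## dense arithmetic wins for small or high-density sub-graphs
  if (n <= spectral_max || Matrix::nnzero(Wsub) > 0.1 * n^2)
    Wsub <- as.matrix(Wsub)
  deg <- if (is.matrix(Wsub)) rowSums(Wsub) else Matrix::rowSums(Wsub)

  finish <- function(side) {
    list(a = idx[side], b = idx[!side],
         cut = cut_weight(Wsub, side), ncut = cut_edges(Wsub, side))
  }
  if (n == 2) return(finish(c(TRUE, FALSE)))

  ## disconnected sub-graph: grouping whole components dissolves nothing
  comp <- components_of(if (is.matrix(Wsub))
    methods::as(methods::as(Matrix::Matrix(Wsub, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
    else Wsub)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    ord <- order(-sizes, seq_along(sizes))
    s1 <- 0L; s2 <- 0L; take <- logical(length(sizes))
    for (cmp in ord) {                 # greedy balance of components
      if (s1 <= s2) { take[cmp] <- TRUE; s1 <- s1 + sizes[cmp] }
      else s2 <- s2 + sizes[cmp]
    }
    side <- take[comp]
    if (sum(side) >= minside && sum(!side) >= minside)
      return(finish(side))             # zero cut, cannot be beaten
  }

  candidates <- list()
  if (is.matrix(Wsub) && n <= 1500L) { # spectral ordering (Fiedler vector)
    L <- diag(deg) - Wsub
    ev <- eigen(L, symmetric = TRUE)
    fied <- ev$vectors[, n - 1L]
    ord <- order(fied, seq_len(n))
    candidates <- c(candidates, list(best_prefix_side(Wsub, deg, ord,
                                                      minside)))
  }
  starts <- if (length(candidates)) which.min(deg)  # spectral present
            else unique(c(which.min(deg), which.max(deg)))
  for (start in starts) {
    ord <- growth_order(Wsub, deg, start)
    candidates <- c(candidates, list(best_prefix_side(Wsub, deg, ord,
                                                      minside)))
  }
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) {           # balance infeasible in sweep: halve
    side <- rep(FALSE, n); side[seq_len(n %/% 2L)] <- TRUE
    candidates <- list(side)
  }
  best <- NULL; bestcut <- Inf
  for (side in candidates) {
    side <- fm_refine(Wsub, deg, side, minside)
    cw <- cut_weight(Wsub, side)
    if (cw < bestcut - 1e-12) { bestcut <- cw; best <- side }
  }
  finish(best)
}

#' Partition a neighbour graph into sub-partitions by min-weight bisection
#'
#' Recursive bisection: at each step one current sub-partition is bisected so
#' as to (heuristically) minimize the total similarity weight of the
#' dissolved edges, subject to a balance floor (each side of a bisection must
#' hold at least `balance_floor` of the bisected set's vertices).  With
#' `prioritize_large` the largest sub-partition is always bisected next;
#' otherwise the sub-partition whose best bisection dissolves the least
#' weight per dissolved edge is chosen.  All tie-breaks are by lowest vertex
#' index, so the procedure is deterministic.
#'
#' @param g a [neighbor_graph()].
#' @param a number of sub-partitions to produce (1..n).
#' @param prioritize_large always bisect the largest sub-partition next.
#' @param seed accepted for interface uniformity; the partitioner is
#'   deterministic and does not consume randomness.
#' @param balance_floor minimum fraction of a bisected set on each side
#'   (default 0.025).
#' @return Integer label vector (1..a), named by sample id.
#' @export
partition_graph <- function(g, a, prioritize_large = FALSE, seed = NULL,
                            balance_floor = 0.025) {
  stopifnot(inherits(g, "neighbor_graph"))
  n <- g$n_vertices
  a <- as.integer(a)
  if (is.na(a) || a < 1 || a > n)
    stop(sprintf("a must be in [1, %d]", n), call. = FALSE)
  W <- g$adjacency
  clusters <- list(seq_len(n))
  cache <- list(NULL)
  while (length(clusters) < a) {
    sizes <- lengths(clusters)
    cand <- which(sizes >= 2L)
    if (prioritize_large) {
      firsts <- vapply(clusters[cand], min, integer(1))
      pick <- cand[order(-sizes[cand], firsts)[1]]
      if (is.null(cache[[pick]]))
        cache[[pick]] <- best_bisection(W, clusters[[pick]], balance_floor)
    } else {
      for (ci in cand) if (is.null(cache[[ci]]))
        cache[[ci]] <- best_bisection(W, clusters[[ci]], balance_floor)
      ratio <- vapply(cache[cand], function(b)
        b$cut / max(1L, b$ncut), numeric(1))
      cuts <- vapply(cache[cand], function(b) b$cut, numeric(1))
      firsts <- vapply(clusters[cand], min, integer(1))
      pick <- cand[order(ratio, cuts, firsts)[1]]
    }
    bb <- cache[[pick]]
    clusters[[pick]] <- bb$a
    cache[pick] <- list(NULL)
    clusters[[length(clusters) + 1L]] <- bb$b
    cache[length(clusters)] <- list(NULL)
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels <- normalize_labels(labels)
  names(labels) <- g$sample_ids
  labels
}

## --- internal: cluster-pair linkage bookkeeping on the edge list ---------

pair_linkage_table <- function(ci, cj, w, sizes, linkage) {
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  keep <- lo != hi
  lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
  key <- paste(lo, hi)
  if (!length(key))
    return(data.frame(a = integer(0), b = integer(0), link = numeric(0)))
  agg_max <- tapply(w, key, max)
  agg_min <- tapply(w, key, min)
  agg_n <- tapply(w, key, length)
  ab <- do.call(rbind, strsplit(names(agg_max), " ", fixed = TRUE))
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  link <- if (linkage == "single") as.numeric(agg_max) else {
    full <- sizes[a] * sizes[b]
    ifelse(as.numeric(agg_n) < full, 0, as.numeric(agg_min))
  }
  data.frame(a = a, b = b, link = link)
}

#' Merge sub-partitions by graph-based hierarchical agglomeration
#'
#' Greedy agglomeration of an existing sub-partition: at each step the pair
#' of clusters with the highest linkage similarity is merged.  With
#' `linkage = "single"` the linkage is the maximum weight over graph edges
#' joining the two clusters; with `linkage = "complete"` it is the minimum
#' over all joining vertex pairs, where pairs not connected by a graph edge
#' contribute weight 0.  Cluster pairs sharing no edge at all have linkage
#' -Inf and merge only when no connected pair remains.  With
#' `on = "matrix"` the full similarity matrix is used instead of graph
#' edges.
#'
#' @param g a [neighbor_graph()].
#' @param labels integer sub-partition labels (from [partition_graph()]).
#' @param k_final number of clusters to stop at.
#' @param linkage `"single"` or `"complete"`.
#' @param on evaluate linkage on `"graph"` edges (default) or on the full
#'   similarity `"matrix"`.
#' @param sim similarity matrix, required when `on = "matrix"`.
#' @return Integer label vector with `k_final` clusters; attribute
#'   `merge_history` lists, per merge, the member sets of the two merged
#'   clusters.
#' @export
agglomerate_subpartitions <- function(g, labels, k_final,
                                      linkage = c("complete", "single"),
                                      on = c("graph", "matrix"),
                                      sim = NULL) {
  linkage <- match.arg(linkage)
  on <- match.arg(on)
  labels <- normalize_labels(as.integer(labels))
  m <- max(labels)
  k_final <- as.integer(k_final)
  if (k_final > m)
    stop(sprintf("k_final (%d) exceeds current cluster count (%d)",
                 k_final, m), call. = FALSE)
  if (on == "matrix") {
    if (is.null(sim)) stop("on = \"matrix\" requires `sim`", call. = FALSE)
    sim <- as_similarity(sim)
    idx <- which(upper.tri(sim), arr.ind = TRUE)
    e_i <- idx[, 1]; e_j <- idx[, 2]; e_w <- sim[idx]
  } else {
    idx <- Matrix::summary(g$adjacency)
    keep <- idx$i < idx$j
    e_i <- idx$i[keep]; e_j <- idx$j[keep]; e_w <- idx$x[keep]
  }
  memb <- labels                       # vertex -> current cluster
  history <- list()
  while (max(memb) > k_final) {
    sizes <- tabulate(memb)
    tab <- pair_linkage_table(memb[e_i], memb[e_j], e_w, sizes, linkage)
    if (nrow(tab)) {
      best <- order(-tab$link, tab$a, tab$b)[1]
      pa <- tab$a[best]; pb <- tab$b[best]
    } else {                           # no connected pair: lowest indices
      pa <- 1L; pb <- 2L
    }
    history[[length(history) + 1L]] <-
      list(a = which(memb == pa), b = which(memb == pb))
    memb[memb == pb] <- pa
    memb <- normalize_labels(memb)
  }
  out <- normalize_labels(memb)
  names(out) <- names(labels)
  attr(out, "merge_history") <- history
  out
}

#' Two-phase Chameleon-style clustering
#'
#' Composition of the three stages: build a k-nearest-neighbour similarity
#' graph ([build_knn_graph()]), partition it into `a` sub-partitions by
#' recursive min-weight bisection ([partition_graph()]), then merge
#' sub-partitions down to `k_final` clusters by graph-based agglomeration
#' ([agglomerate_subpartitions()]).  When `a = k_final` (the default) the
#' agglomerative phase is omitted and the partitioning alone yields the
#' solution.
#'
#' @param sim a [similarity_matrix()].
#' @param k_neighbors neighbourhood size for the sparse graph.
#' @param k_final number of clusters in the solution.
#' @param a number of sub-partitions (`k_final <= a <= n`); defaults to
#'   `k_final`.
#' @param linkage agglomeration linkage, `"complete"` (default) or
#'   `"single"`.
#' @param prioritize_large bisect the largest sub-partition first during
#'   partitioning.
#' @param seed recorded in the solution; the pipeline is deterministic.
#' @param balance_floor per-bisection balance floor, see
#'   [partition_graph()].
#' @param linkage_on `"graph"` or `"matrix"`, see
#'   [agglomerate_subpartitions()].
#' @return A [cluster_solution()].
#' @examples
#' pts <- simulate_gaussian_clusters(centroids = list(c(0, 0), c(10, 0)),
#'                                   sizes = c(20, 20), sd = 1, seed = 1)
#' sim <- points_to_similarity(pts$points)
#' sol <- chameleon_cluster(sim, k_neighbors = 5, k_final = 2)
#' table(sol$labels, pts$labels)
#' @export
chameleon_cluster <- function(sim, k_neighbors, k_final, a = NULL,
                              linkage = c("complete", "single"),
                              prioritize_large = FALSE, seed = NULL,
                              balance_floor = 0.025,
                              linkage_on = c("graph", "matrix")) {
  linkage <- match.arg(linkage)
  linkage_on <- match.arg(linkage_on)
  sim <- as_similarity(sim)
  n <- nrow(sim)
  if (is.null(a)) a <- k_final
  if (k_final > a)
    stop("a (sub-partitions) must be >= k_final (clusters)", call. = FALSE)
  if (a > n) stop("a exceeds the number of samples", call. = FALSE)
  g <- build_knn_graph(sim, k_neighbors)
  labels <- partition_graph(g, a, prioritize_large = prioritize_large,
                            seed = seed, balance_floor = balance_floor)
  used_linkage <- "none"
  if (a > k_final) {
    labels <- agglomerate_subpartitions(g, labels, k_final,
                                        linkage = linkage, on = linkage_on,
                                        sim = sim)
    used_linkage <- linkage
  }
  cluster_solution(
    stats::setNames(as.integer(labels), rownames(sim)),
    params = list(algorithm = "chameleon", k = k_final,
                  k_neighbors = k_neighbors, a = a, linkage = used_linkage,
                  prioritize_large = prioritize_large, seed = seed,
                  balance_floor = balance_floor, linkage_on = linkage_on))
}
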