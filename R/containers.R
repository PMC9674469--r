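#' Plot-by-species community matrix
#'
#' Light S3 container for a plots x species matrix of non-negative abundances
#' or 0/1 incidences.  Row names are plot identifiers, column names are
#' species identifiers; both must be unique.
#'
#' @param values numeric matrix, plots in rows, species in columns, with
#'   unique `rownames` (plot ids) and `colnames` (species ids).
#' @return An object of class `community_matrix`: the validated matrix with
#'   attribute `is_binary` (`TRUE` iff all entries are 0 or 1).
#' @examples
#' m <- matrix(c(1, 0, 0, 2), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("sp1", "sp2")))
#' cm <- community_matrix(m)
#' attr(cm, "is_binary")
#' @export
community_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("community matrix needs plot (row) and species (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate plot identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate species identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values)) stop("community matrix contains missing values",
                          call. = FALSE)
  if (any(values < 0)) stop("community matrix contains negative values",
                            call. = FALSE)
  structure(values,
            is_binary = all(values == 0 | values == 1),
            class = c("community_matrix", class(matrix())))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d plots x %d species (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_binary"))) "presence-absence"
              else "abundance"))
  invisible(x)
}

#' Pairwise similarity matrix
#'
#' Symmetric n x n matrix of similarities in \[0, 1\] with unit diagonal.
#' Sample identifiers are carried as dimnames (generated as `s1..sn` when
#' absent).
#'
#' @param values symmetric numeric matrix with entries in \[0, 1\].
#' @param tol tolerance for the symmetry check (default `1e-9`).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values) || nrow(values) == 0)
    stop("similarity matrix must be square and non-empty", call. = FALSE)
  if (anyNA(values)) stop("similarity matrix contains missing values",
                          call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("similarity matrix is asymmetric (max deviation %.3g)",
                 asym), call. = FALSE)
  values <- (values + t(values)) / 2
  if (any(values < -tol) || any(values > 1 + tol))
    stop("similarity values outside [0, 1]", call. = FALSE)
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  if (is.null(rownames(values))) {
    ids <- paste0("s", seq_len(nrow(values)))
    dimnames(values) <- list(ids, ids)
  }
  colnames(values) <- rownames(values)
  structure(values, class = c("similarity_matrix", class(matrix())))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d samples, mean off-diagonal %.3f\n",
              nrow(x), mean(x[upper.tri(x)])))
  invisible(x)
}

as_similarity <- function(sim, tol = 1e-9) {
  if (inherits(sim, "similarity_matrix")) return(sim)
  similarity_matrix(as.matrix(sim), tol = tol)
}

#' Weighted k-nearest-neighbour graph over samples
#'
#' @param adjacency symmetric sparse `Matrix` of edge weights (0 = no edge,
#'   no self-loops).
#' @param k_neighbors the neighbourhood size used to build the graph.
#' @param sample_ids character vector of vertex identifiers.
#' @return An object of class `neighbor_graph` with elements `adjacency`,
#'   `n_vertices`, `k_neighbors`, `sample_ids`.
#' @seealso [build_knn_graph()]
#' @export
neighbor_graph <- function(adjacency, k_neighbors, sample_ids = NULL) {
  adjacency <- methods::as(methods::as(adjacency, "generalMatrix"),
                           "CsparseMatrix")
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("adjacency must be square", call. = FALSE)
  if (any(Matrix::diag(adjacency) != 0))
    stop("self-edges are not allowed", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  structure(list(adjacency = adjacency,
                 n_vertices = n,
                 k_neighbors = k_neighbors,
                 sample_ids = sample_ids),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  m <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("neighbor_graph: %d vertices, %d edges (k = %d)\n",
              x$n_vertices, m, x$k_neighbors))
  invisible(x)
}

#' Clustering solution
#'
#' Integer cluster labels for each sample, together with the parameters that
#' generated them.
#'
#' @param labels integer vector of cluster indices (1-based, consecutive),
#'   optionally named by sample id.
#' @param params named list of generating parameters (algorithm, k, ...).
#' @return Object of class `cluster_solution` with elements `labels` and
#'   `params`.
#' @export
cluster_solution <- function(labels, params = list()) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  structure(list(labels = labels, params = params),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("cluster_solution (%s): %d samples in %d clusters\n",
              x$params$algorithm %||% "?", length(x$labels), length(sizes)))
  cat("  sizes:", paste(utils::head(as.integer(sizes), 12), collapse = " "),
      if (length(sizes) > 12) "...\n" else "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## relabel clusters 1..k in order of each cluster's lowest member index,
## so solutions are invariant to internal bookkeeping order
normalize_labels <- function(labels) {
  first <- tapply(seq_along(labels), labels, min)
  ord <- rank(first, ties.method = "first")
  as.integer(ord[as.character(labels)])
}
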