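#' Species-by-cluster diagnostic table
#'
#' For every (species, cluster) pair, tabulates `x` (occurrences in the
#' cluster), `m` (cluster size), `X` (occurrences in the whole dataset),
#' `N` (total plots) and the in-cluster frequency `x/m`, then scores the
#' pair by the cumulative hypergeometric tail and by the standardized phi
#' fidelity coefficient.
#'
#' The hypergeometric tail is `P(H < x)` with
#' `H ~ Hypergeometric(N, X, m)`: a species is concentration-diagnostic
#' when its in-cluster frequency is statistically higher than its background
#' frequency, i.e. the tail exceeds `p_threshold` (an upper-tail test at
#' level `1 - p_threshold`).  `tail = "inclusive"` uses `P(H <= x)`
#' instead.
#'
#' Phi is the 2x2 association coefficient
#' `(N x - m X) / sqrt(m X (N - m)(N - X))`; the standardized variant
#' recomputes it after rescaling the target cluster to relative size
#' `standardize_size` (default `1/k`, equal cluster sizes) while preserving
#' the in-cluster and out-of-cluster relative frequencies, so fidelity is
#' comparable across clusters of unequal size.  A species present in no or
#' in all plots has phi 0 by convention.
#'
#' No multiple-testing correction is applied by default (`p_adjust =
#' "none"`); a correction method from [stats::p.adjust()] can be requested,
#' in which case the adjusted upper-tail p-value `1 - P(H < x)` is compared
#' against `1 - p_threshold`.
#'
#' @param m a binary [community_matrix()].
#' @param labels cluster labels (vector or [cluster_solution()]).
#' @param p_threshold hypergeometric tail threshold (default 0.999).
#' @param phi_threshold standardized phi threshold (default 0.35, compared
#'   with `>=`).
#' @param standardize standardize phi to equal cluster sizes (default TRUE).
#' @param standardize_size target relative cluster size; default `1/k`.
#' @param tail `"strict"` (`P(H < x)`, default) or `"inclusive"`
#'   (`P(H <= x)`).
#' @param p_adjust multiple-testing correction method, default `"none"`.
#' @return `data.frame` of class `diagnostic_table` with one row per
#'   (species, cluster) pair and columns `species`, `cluster`, `x`, `m`,
#'   `X`, `N`, `in_cluster_frequency`, `hypergeom_p`, `phi`,
#'   `diag_hypergeom`, `diag_phi`.
#' @export
diagnostic_table <- function(m, labels, p_threshold = 0.999,
                             phi_threshold = 0.35, standardize = TRUE,
                             standardize_size = NULL,
                             tail = c("strict", "inclusive"),
                             p_adjust = "none") {
  tail <- match.arg(tail)
  if (!inherits(m, "community_matrix")) m <- community_matrix(m)
  if (!isTRUE(attr(m, "is_binary")))
    stop("diagnostics require presence-absence data", call. = FALSE)
  labels <- solution_labels(labels)
  if (length(labels) != nrow(m))
    stop("labels length mismatch", call. = FALSE)
  N <- nrow(m)
  X <- colSums(m)
  clusters <- sort(unique(labels))
  k <- length(clusters)
  rows <- lapply(clusters, function(c) {
    members <- labels == c
    mc <- sum(members)
    x <- colSums(unclass(m)[members, , drop = FALSE])
    p <- if (tail == "strict") stats::phyper(x - 1, X, N - X, mc)
         else stats::phyper(x, X, N - X, mc)
    s <- if (standardize) standardize_size %||% (1 / k) else mc / N
    phi <- phi_coefficient(x, mc, X, N, target_size = s)
    data.frame(species = colnames(m), cluster = c, x = as.integer(x),
               m = mc, X = as.integer(X), N = N,
               in_cluster_frequency = x / mc,
               hypergeom_p = p, phi = phi, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    upper <- stats::p.adjust(1 - out$hypergeom_p, method = p_adjust)
    out$diag_hypergeom <- upper < (1 - p_threshold)
  } else {
    out$diag_hypergeom <- out$hypergeom_p > p_threshold
  }
  out$diag_phi <- out$phi >= phi_threshold
  class(out) <- c("diagnostic_table", "data.frame")
  out
}

## phi of the 2x2 (in cluster x species present) table, optionally after
## rescaling the cluster to relative size `target_size` with in/out
## frequencies preserved.  Degenerate margins give 0.
phi_coefficient <- function(x, mc, X, N, target_size = NULL) {
  if (is.null(target_size)) {
    num <- N * x - mc * X
    den2 <- as.numeric(mc) * X * (N - mc) * (N - X)
    phi <- ifelse(den2 > 0, num / sqrt(den2), 0)
  } else {
    s <- target_size
    f_in <- x / mc
    f_out <- if (all(N - mc > 0)) (X - x) / (N - mc) else rep(0, length(x))
    xp <- s * f_in
    Xp <- s * f_in + (1 - s) * f_out
    den2 <- s * Xp * (1 - s) * (1 - Xp)
    phi <- ifelse(den2 > 0, (xp - s * Xp) / sqrt(den2), 0)
  }
  pmin(1, pmax(-1, phi))
}

#' Hypergeometric concentration diagnostics
#'
#' Convenience wrapper around [diagnostic_table()] retaining the
#' hypergeometric columns only.
#'
#' @inheritParams diagnostic_table
#' @return A `diagnostic_table` (phi columns present but computed with
#'   defaults).
#' @export
hypergeometric_diagnostics <- function(m, labels, p_threshold = 0.999,
                                       tail = c("strict", "inclusive")) {
  diagnostic_table(m, labels, p_threshold = p_threshold, tail = tail)
}

#' Standardized phi fidelity diagnostics
#'
#' Convenience wrapper around [diagnostic_table()] for the phi criterion.
#'
#' @inheritParams diagnostic_table
#' @export
phi_diagnostics <- function(m, labels, phi_threshold = 0.35,
                            standardize = TRUE, standardize_size = NULL) {
  labels <- solution_labels(labels)
  if (length(unique(labels)) < 2)
    stop("phi diagnostics need at least two clusters", call. = FALSE)
  diagnostic_table(m, labels, phi_threshold = phi_threshold,
                   standardize = standardize,
                   standardize_size = standardize_size)
}

#' Summarize diagnostic counts for a solution
#'
#' Per-solution totals in the style of a diagnostic-species summary table:
#' the number of (species, cluster) pairs passing the hypergeometric
#' criterion, passing it jointly with an in-cluster frequency floor, and the
#' same for the phi criterion; medians of the in-cluster frequency of the
#' joint passers are reported alongside.  With `unique_species = TRUE`
#' species are counted once even if diagnostic of several clusters.
#'
#' @param table a `diagnostic_table`.
#' @param freq_threshold in-cluster frequency floor (default 0.3).
#' @param unique_species count unique species instead of
#'   (species, cluster) pairs.
#' @return One-row `data.frame` with counts and median frequencies (NA when
#'   there are no passers).
#' @export
diagnostic_counts <- function(table, freq_threshold = 0.3,
                              unique_species = FALSE) {
  if (!nrow(table)) stop("empty diagnostic table", call. = FALSE)
  count <- function(flag) {
    if (unique_species) length(unique(table$species[flag])) else sum(flag)
  }
  hg <- table$diag_hypergeom
  hgf <- hg & table$in_cluster_frequency >= freq_threshold
  ph <- table$diag_phi
  phf <- ph & table$in_cluster_frequency >= freq_threshold
  med <- function(flag) if (any(flag))
    stats::median(table$in_cluster_frequency[flag]) else NA_real_
  data.frame(
    n_hypergeom = count(hg),
    n_hypergeom_freq = count(hgf),
    median_freq_hypergeom = med(hgf),
    n_phi = count(ph),
    n_phi_freq = count(phf),
    median_freq_phi = med(phf))
}

#' Confusion matrix against a reference classification
#'
#' Each cell holds the proportion of a reference class's indicative species
#' that were identified as diagnostic of a cluster:
#' `|ref(class) intersect diag(cluster)| / |ref(class)|`.  Diagnostic
#' species of a cluster are the rows of `diag` with the hypergeometric flag
#' set (the concentration criterion).
#'
#' @param diag a `diagnostic_table`.
#' @param ref a `reference_classification` (named list class -> species).
#' @param criterion which diagnostic flag defines a cluster's species set.
#' @return Numeric matrix, reference classes in rows (reference order),
#'   clusters in columns.
#' @export
reference_confusion <- function(diag, ref,
                                criterion = c("hypergeom", "phi")) {
  criterion <- match.arg(criterion)
  flag <- if (criterion == "hypergeom") diag$diag_hypergeom else
    diag$diag_phi
  if (any(!lengths(ref))) stop("empty reference class", call. = FALSE)
  clusters <- sort(unique(diag$cluster))
  sets <- lapply(clusters, function(c)
    unique(diag$species[flag & diag$cluster == c]))
  out <- t(vapply(ref, function(spp)
    vapply(sets, function(dg) length(intersect(spp, dg)) / length(spp),
           numeric(1)),
    numeric(length(clusters))))
  dimnames(out) <- list(names(ref), as.character(clusters))
  out
}

#' Write a diagnostic table or confusion matrix as delimited text
#'
#' @param x a `diagnostic_table` or matrix.
#' @param path output path.
#' @export
write_diagnostics <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(class = rownames(x), as.data.frame(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
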