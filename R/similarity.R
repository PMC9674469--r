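#' Transform a community matrix to presence-absence
#'
#' Any positive abundance becomes 1; the result is flagged binary.  The
#' transform is idempotent.  All-zero plots survive the transform (an empty
#' plot carries no information either way) but are rejected by
#' [bray_curtis_similarity()].
#'
#' @param m a [community_matrix()].
#' @return A binary [community_matrix()].
#' @export
to_presence_absence <- function(m) {
  if (!inherits(m, "community_matrix")) m <- community_matrix(m)
  out <- (unclass(m) > 0) * 1
  dimnames(out) <- dimnames(m)
  community_matrix(out)
}

#' Pairwise Bray-Curtis (Sorensen-Dice) similarity on presence-absence data
#'
#' For binary data the Bray-Curtis similarity between plots i and j is
#' `2a / (2a + b + c)` where `a` is the number of shared species and `b`,
#' `c` the numbers unique to each plot.  Distances are computed with
#' [vegan::vegdist()] and converted to similarities.
#'
#' Species observed in no plot are dropped with a warning before computation:
#' they cannot affect any pairwise score but distort frequency-based
#' diagnostics.  Plots with zero species are an error (their similarity to
#' anything is undefined).
#'
#' @param m a binary [community_matrix()] (use [to_presence_absence()]
#'   first).
#' @return A [similarity_matrix()] with the plot ids of `m`.
#' @export
bray_curtis_similarity <- function(m) {
  if (!inherits(m, "community_matrix")) m <- community_matrix(m)
  if (!isTRUE(attr(m, "is_binary")))
    stop("similarity expects presence-absence data; ",
         "apply to_presence_absence() first", call. = FALSE)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    stop("plot(s) with zero species: ",
         paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
  ghost <- colSums(m) == 0
  if (any(ghost)) {
    warning(sum(ghost), " species occur in no plot; dropping them")
    m <- community_matrix(unclass(m)[, !ghost, drop = FALSE])
  }
  d <- vegan::vegdist(unclass(m), method = "bray", binary = TRUE)
  s <- 1 - as.matrix(d)
  dimnames(s) <- list(rownames(m), rownames(m))
  similarity_matrix(s)
}
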