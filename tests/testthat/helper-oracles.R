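## Independent brute-force oracles and small fixture generators.  Every
## oracle here is written against the definition of the quantity, not
## against the package implementation it checks.

random_similarity <- function(n, seed, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  s <- matrix(stats::runif(n * n, lo, hi), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  similarity_matrix(s)
}

random_binary_community <- function(n_plots, n_species, seed, p = 0.4) {
  set.seed(seed)
  repeat {
    v <- matrix(stats::rbinom(n_plots * n_species, 1, p), n_plots,
                dimnames = list(paste0("p", seq_len(n_plots)),
                                paste0("sp", seq_len(n_species))))
    if (all(rowSums(v) > 0) && all(colSums(v) > 0)) break
    seed <- seed + 1000
    set.seed(seed)
  }
  community_matrix(v)
}

## Sorensen similarity by explicit set arithmetic
oracle_sorensen <- function(row_i, row_j) {
  a <- sum(row_i == 1 & row_j == 1)
  b <- sum(row_i == 1 & row_j == 0)
  cc <- sum(row_i == 0 & row_j == 1)
  2 * a / (2 * a + b + cc)
}

## misplacement by a double-loop nearest-neighbour scan
oracle_misplacement <- function(s, labels) {
  n <- nrow(s)
  bad <- 0
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(n)) if (j != i && s[i, j] > best) best <- s[i, j]
    nn <- c()
    for (j in seq_len(n)) if (j != i && s[i, j] == best) nn <- c(nn, j)
    if (!any(labels[nn] == labels[i])) bad <- bad + 1
  }
  bad / n
}

## homogeneity by explicit pair enumeration
oracle_homogeneity <- function(s, labels) {
  vals <- c()
  for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s))
    if (labels[i] == labels[j]) vals <- c(vals, s[i, j])
  mean(vals)
}

## k-NN edge set by per-row sort with union symmetrization
oracle_knn_edges <- function(s, k) {
  n <- nrow(s)
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    vals <- s[i, others]
    kth <- sort(vals, decreasing = TRUE)[k]
    sel[i, others[vals >= kth]] <- TRUE
  }
  sel <- sel | t(sel)
  which(sel & upper.tri(sel), arr.ind = TRUE)
}

## lower tail P(H < x) by direct pmf enumeration over the support
oracle_hyper_tail <- function(x, N, X, m) {
  lo <- max(0, m + X - N)
  hi <- min(m, X)
  support <- lo:hi
  pmf <- choose(X, support) * choose(N - X, m - support) / choose(N, m)
  sum(pmf[support < x])
}

## exhaustive minimum-cut balanced bisection (n <= 14)
oracle_min_bisection <- function(W, minside) {
  n <- nrow(W)
  best <- Inf
  for (mask in seq_len(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    k1 <- sum(side)
    if (k1 < minside || (n - k1) < minside) next
    cut <- sum(W[side, !side])
    if (cut < best) best <- cut
  }
  best
}

## random sparse weighted graph as dense symmetric matrix
random_graph_matrix <- function(n, p = 0.45) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) W[i, j] <- W[j, i] <- stats::runif(1)
  W
}

as_sparse_general <- function(W) {
  methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

## step-by-step Lance-Williams flexible-beta recurrence on a working copy
## of the dissimilarity matrix, clusters tracked as explicit member lists
oracle_lw_flexible <- function(d0, beta, steps) {
  clusters <- as.list(seq_len(nrow(d0)))
  d <- d0
  out <- list()
  for (st in seq_len(steps)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    ai <- (1 - beta) * ni / (ni + nj)
    aj <- (1 - beta) * nj / (ni + nj)
    newrow <- sapply(seq_len(m), function(k)
      ai * d[i, k] + aj * d[j, k] + beta * d[i, j])
    out[[st]] <- list(a = clusters[[i]], b = clusters[[j]],
                      height = best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    d[i, ] <- newrow; d[, i] <- newrow
    clusters <- clusters[-j]
    d <- d[-j, -j, drop = FALSE]
    if (length(clusters) > 1) diag(d) <- 0
  }
  out
}

## direct simulation of the splinter-group division rules
oracle_splinter <- function(d, members) {
  dm <- d[members, members, drop = FALSE]
  m <- length(members)
  mean_rest <- rowSums(dm) / (m - 1)
  spl <- which.max(mean_rest)
  in_spl <- rep(FALSE, m)
  in_spl[spl] <- TRUE
  repeat {
    nr <- sum(!in_spl)
    if (nr <= 1) break
    gains <- rep(-Inf, m)
    for (v in which(!in_spl)) {
      to_s <- mean(dm[v, in_spl])
      to_r <- sum(dm[v, !in_spl]) / (nr - 1)
      gains[v] <- to_r - to_s
    }
    v <- which.max(gains)
    if (gains[v] <= 0) break
    in_spl[v] <- TRUE
  }
  members[in_spl]
}

## do two label vectors describe the same partition?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## partition after `step` merges of a recorded merge history
partition_after <- function(history, n, step) {
  labs <- seq_len(n)
  for (st in seq_len(step)) {
    h <- history[[st]]
    labs[c(h$a, h$b)] <- min(labs[c(h$a, h$b)])
  }
  labs
}
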