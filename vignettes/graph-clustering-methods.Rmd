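---
title: "Interconnectivity-based clustering of community data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interconnectivity-based clustering of community data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Vegetation classification clusters plot samples (relevés) by compositional
similarity.  Most traditional algorithms — k-means, group-average
agglomeration, polythetic division — optimize central tendency and
implicitly assume compact, roughly spheroidal clusters of comparable
density.  Field data rarely cooperate: sampling is uneven, gradients
produce elongated structures, and dense clusters sit next to sparse ones.
A central-tendency optimizer will then happily split a dense cluster to
"buy" variance reduction while merging two sparse distant ones.

`chamclust` implements a two-phase graph-theoretic alternative in the
style of the Chameleon algorithm, together with the traditional baselines,
internal evaluation metrics that measure *interconnectivity* rather than
compactness, diagnostic-species scoring, and synthetic-data generators
that emulate the data structures at issue.

# The two-phase graph algorithm

Let $S$ be an $n \times n$ matrix of pairwise similarities, here the
Sørensen (binary Bray–Curtis) index $s = 2a/(2a+b+c)$ on presence–absence
data, or a distance-derived similarity for point clouds.

**Phase 0 — sparse graph.**  Each sample is linked to its $k$ most
similar other samples (`k_neighbors`, the *neighbourhood size*); ties at
the $k$-th rank are all included so the graph does not depend on input
order.  The directed lists are union-symmetrized (an edge survives if
either endpoint chose the other), which preserves the connectivity of
low-degree outliers.  Edge weight equals similarity.

**Phase 1 — partitioning.**  The graph is divided into `a`
*sub-partitions* by recursive bisection.  Each bisection heuristically
minimizes the summed similarity of dissolved edges — the affinity between
the two sides — subject to a balance floor: each side must hold at least
`balance_floor` (default 2.5%) of the bisected set.  A bisection is
initialized from the Fiedler (spectral) ordering of the sub-graph
Laplacian, with all admissible prefix cuts of the ordering scanned, plus a
greedy max-connection growth ordering; each candidate is refined by
Fiduccia–Mattheyses-style passes (best-gain moves with rollback to the
best prefix).  Disconnected sub-graphs are first split along whole
components, which dissolves nothing.  All tie-breaks are by lowest vertex
index, so the partitioner is fully deterministic; the `seed` argument is
recorded but never consumed.

Which sub-partition is bisected next is governed by `prioritize_large`:
either the largest one (recommended for data with strong density
contrasts, see below), or the one whose best bisection dissolves the least
weight per dissolved edge.

**Phase 2 — agglomeration.**  Sub-partitions are merged hierarchically
until `k_final` clusters remain.  Linkage is evaluated *on graph edges*:
single linkage is the maximum weight over edges joining two clusters;
complete linkage is the minimum over all joining vertex pairs with absent
edges counting 0.  Cluster pairs sharing no edge have linkage $-\infty$
and merge only when no connected pair remains.  Setting `a = k_final`
(the default) omits this phase entirely, so the partitioning alone yields
the solution.  An option (`linkage_on = "matrix"`) evaluates linkage on
the full similarity matrix instead; whether the original implementation
uses graph edges or the full matrix is not documented, so both are
available and the pure-graph variant is the default.

## Parameter guidance

| parameter | meaning | default | notes |
|---|---|---|---|
| `k_neighbors` | neighbourhood size of the sparse graph | 15 | larger values force small clusters to link across boundaries and raise misplacement |
| `a` | number of sub-partitions | `k_final` | values well above `k_final` with single linkage invite chaining |
| `k_final` | clusters in the solution | — | |
| `linkage` | phase-2 criterion | complete | complete linkage produces more even clusters |
| `prioritize_large` | bisect largest sub-partition first | `FALSE` | see below |
| `balance_floor` | minimum side fraction per bisection | 0.025 | see below |

**The balance floor.**  An unconstrained minimum cut degenerates to
shaving single vertices off the graph's fringe.  A floor of 10% per side
would prevent that entirely, but it also makes any cluster smaller than
10% of its parent set unrecoverable — and uneven cluster sizes are
precisely the regime this algorithm targets (the bundled presets contain
clusters of 1.6% of the data).  The default of 2.5% is chosen so that
single-vertex shaving is blocked on any set larger than 40 vertices while
clusters at the size ratios of the bundled simulations remain separable.
The floor is a per-bisection constraint and is exposed as an argument.

**Choosing the sub-partition to bisect.**  The least-weight-per-dissolved-
edge rule is scale-sensitive: on similarity matrices where within-cluster
edges are only slightly stronger than between-cluster edges (as happens
with globally normalized point distances), shaving a handful of weak
fringe edges off a small sparse cluster can undercut a genuine
between-cluster bisection.  With strong density contrasts we therefore
recommend, and use in the package's own demonstrations,
`prioritize_large = TRUE`, which always bisects the largest current
sub-partition — the same remedy the original software documentation
recommends against chaining-type degeneracies.

# Baselines

* `kmeans_points()` — Lloyd iteration on coordinates, best of
  `n_restarts` random initializations by within-cluster sum of squares.
  Used for point-cloud data.
* `kmedoids_dissimilarity()` — PAM-style alternation (assign to most
  similar medoid, re-seat medoid to maximize within-cluster similarity)
  on the similarity matrix; the nonhierarchical-allocation baseline for
  community data.  Which of the two spaces a given comparison used is
  always stated in its documentation, since the two are not equivalent.
* `flexible_upgma()` — Lance–Williams flexible-beta agglomeration with
  group-size (arithmetic) weighting; `beta = 0` is plain UPGMA.  The
  default `beta = -0.1` follows common ecological practice; merge heights
  are monotone for `beta <= 0`.
* `polythetic_division()` — splinter-group division: the cluster with the
  highest mean within-cluster dissimilarity (or largest diameter, as an
  option) is divided by seeding a splinter with the most average-distant
  member and moving members while their affinity margin to the splinter
  is positive.

# Evaluation metrics

**Misplacement rate** is the proportion of samples whose nearest
neighbour (by similarity) lies in a different cluster.  Ties are resolved
in the sample's favour: a sample counts as misplaced only if *no* tied
nearest neighbour shares its cluster, so only unambiguous violations are
penalized.  Merging clusters can never increase the rate.

**Homogeneity** is the average pairwise within-cluster similarity, pooled
over all within-cluster pairs across clusters (singletons contribute no
pairs).  Pooling weights large clusters by their pair counts; a
mean-of-cluster-means variant is available via `pooled = FALSE`, since
the conventional phrasing of the metric does not dictate the weighting.

**Evenness profile** ranks cluster sizes ascending as proportions of the
largest cluster, the standard visual for detecting chaining; the sweep
harness additionally flags solutions whose largest cluster exceeds half
the samples.

# Diagnostic species and reference comparison

For every (species, cluster) pair with $x$ occurrences in a cluster of
$m$ plots, $X$ occurrences in $N$ plots overall:

* **Concentration**: the cumulative hypergeometric tail
  $P(H < x)$, $H \sim \mathrm{Hypergeom}(N, X, m)$.  The strict tail
  makes "frequency statistically higher than background at
  $p > 0.999$" an upper-tail test at level 0.001; an inclusive-tail
  option is provided.  Species present everywhere or nowhere can never be
  flagged (their tail is 0 by degeneracy).
* **Fidelity**: the $2\times2$ phi coefficient
  $\phi = (Nx - mX)/\sqrt{mX(N-m)(N-X)}$, by default *standardized* by
  rescaling the target cluster to relative size $1/k$ while preserving
  in- and out-of-cluster relative frequencies, following the standard
  fidelity-standardization practice, so that clusters of different sizes
  are comparable.  With already-equal cluster sizes the standardized and
  raw values coincide.  The threshold comparison uses $\phi \ge 0.35$.

No multiple-testing correction is applied by default, matching the
raw-threshold convention of diagnostic-species screening; `p_adjust`
enables one.  Summaries count (species, cluster) pairs by default with a
unique-species option, again because the tabulation convention is
ambiguous in common usage.

The confusion matrix against an expert reference classification has
reference classes as rows and cell values
$|{\rm ref}(r) \cap {\rm diag}(c)| / |{\rm ref}(r)|$ — the proportion of
a class's indicative species recovered as diagnostic of cluster $c$.

# Synthetic data

`simulate_gaussian_clusters()` draws six isotropic bivariate-normal
clusters (sd = 1) at markedly uneven sizes: preset `uneven_a` uses sizes
(30, 50, 500, 50, 70, 300), preset `uneven_b` (20, 100, 500, 20, 100,
500).  The centroid coordinates are not dictated by anything and are a
package choice, fully exposed in the API: the defaults place every pair
at least 6 sd apart, with each dense (500-point) cluster flanked by a
sparse cluster at exactly 6 sd — the configuration in which
central-tendency methods are tempted to split the dense cluster and
absorb the sparse one.  `points_to_similarity()` feeds coordinates to the
graph pipeline as $s = 1 - d/d_{\max}$ (a Gaussian-kernel alternative is
provided; the qualitative behaviour only needs to hold under one stated
transformation).

`simulate_community_matrix()` generates presence–absence matrices with
per-cluster private species pools (Bernoulli $p_{\rm in}$ inside,
$p_{\rm out}$ outside), shared species, and an optional latent 1-D
gradient: with `gradient_strength > 0` each private species responds to
an optimum on the gradient with Gaussian decay, producing the chained,
elongated similarity structure of a compositional continuum.  Empty plots
are redrawn at most 100 times and then error, in preference to silent
looping.  The generator records each cluster's private species as planted
ground truth for diagnostic-recovery checks.

What the generators deliberately do *not* emulate: cover–abundance
values, observer bias, spatial autocorrelation, and taxonomic noise.
Passing tests on these simulations therefore demonstrates algorithmic
correctness and the qualitative failure modes of central-tendency
clustering, not performance on any particular survey database.

# Study conditions used by the test-suite and acceptance script

* Point presets as above ($n = 1000$ and $1240$); graph solutions with
  `k_neighbors = 15` (trend checks over 15–500), single linkage where the
  agglomerative phase is exercised, `prioritize_large = TRUE`.
* Community trend checks: 6 clusters × 100 plots (600 plots, 195
  species), $p_{\rm in} = 0.5$, $p_{\rm out} = 0.05$, 15 shared species,
  `gradient_strength = 0.5` — a moderately structured continuum in which
  solutions at $k$ = 5–40 remain meaningful.
* Diagnostic recovery: 5 clusters × 30 plots, $p_{\rm in} = 0.9$,
  $p_{\rm out} = 0.02$.
* Partitioner audits: exhaustive enumeration on random graphs of up to 12
  vertices, where brute force is feasible.

These sizes keep the full suite within a desk-scale run while exercising
every code path at the data shapes the method targets.

# Numerical and degeneracy conventions

* Similarity matrices are symmetrized to machine precision on input;
  asymmetry beyond $10^{-9}$ is an error, and the diagonal is coerced to
  exactly 1 (self-similarity is 1 by definition of the index).
* CLUTO-style text output prints 6 decimals, so a write/read round trip
  is exact to $5\times10^{-7}$.
* Zero-species plots are a hard error rather than similarity 0: under
  the package's data conventions an empty plot signals upstream
  corruption.  Species observed in no plot are dropped with a warning
  before similarity computation — they cannot affect any pairwise score
  but would distort frequency-based diagnostics.
* All stochastic functions take an explicit seed and are pure functions
  of (input, parameters, seed); the graph pipeline is deterministic
  outright, with every tie broken by lowest index.

# Known limitations

* The partitioner is a heuristic; optimality is audited against
  exhaustive enumeration only at small $n$.  On adversarial graphs the
  bisection can exceed the true minimum cut.
* The original merge criterion of the Chameleon publication (relative
  interconnectivity × relative closeness) is deliberately out of scope;
  phase 2 here is plain single/complete linkage over graph edges, as in
  the software distribution that popularized the two-phase scheme.
* The least-cut-per-edge sub-partition selection rule is provided for
  completeness but is fragile under compressed similarity scales (see
  above); prefer `prioritize_large` there.
* Dense similarity matrices are held in memory; the implementation
  targets desk-scale data (thousands of samples), not database scale.
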