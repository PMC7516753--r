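---
title: "Elastic principal graphs: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic principal graphs: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

An elastic principal graph approximates a cloud of points
$X = \{X_i\} \subset \mathbb{R}^m$ by a simple undirected graph $G = (V, E)$
injected into the data space through a map $\phi : V \to \mathbb{R}^m$. The
number of nodes is small compared to the number of points (a useful default
is $|V| \approx \sqrt{N}$), and the graph plus its straight edge segments is
the skeleton onto which points are projected — for dimensionality reduction,
for pseudotime along trajectories, or simply to read off the topology of the
cloud (linear, circular, tree-like, or more complex).

The quality of an injection is measured by a trimmed, penalized error:

$$
U^\phi(X, G) \;=\; \frac{1}{\sum_i w_i}\sum_{j}\;\sum_{K(i) = j}
  w_i\,\min\!\big(\lVert X_i - \phi(V_j)\rVert^2,\; R_0^2\big)
  \;+\; U_E^\phi(G) + U_R^\phi(G),
$$

where $K(i)$ assigns each point to its nearest node. The two elastic terms
are

$$
U_E^\phi(G) = \sum_{E^{(i)}}
  \big[\lambda_i + \alpha\,(\max(2, \deg(E^{(i)}(0)), \deg(E^{(i)}(1))) - 2)\big]
  \,\lVert\phi(E^{(i)}(0)) - \phi(E^{(i)}(1))\rVert^2,
$$

the stretching energy over edges, and

$$
U_R^\phi(G) = \sum_{S^{(j)}} \mu_j\,
  \Big\lVert \phi(S^{(j)}(0)) - \tfrac{1}{k_j}\sum_{i=1}^{k_j}
  \phi(S^{(j)}(i)) \Big\rVert^2,
$$

the deviation from harmonicity of every $k$-star (a node of degree
$k \ge 2$ together with its neighbours). A *harmonic* embedding places each
star centre at the mean of its neighbours; for 2-stars this is a discrete
curvature penalty, and for larger stars its natural generalization to
branching points. Only *primitive* elastic graphs are supported: the star
selection is implied by the graph structure, and leaves carry $\mu = 0$.

The harmonicity term can equivalently be written as a system of positive
springs (centre to leaf, moduli $\mu_j / k_j$) and repulsive springs between
leaf pairs (moduli $-\mu_j / k_j^2$). This makes the whole elastic energy a
quadratic form in the node positions: with $\Lambda$ the weighted adjacency
of (effective) edge moduli, $\Lambda_{se}$ and $\Lambda_{sl}$ the two star
spring systems, the summed Laplacian
$\tilde L = L(\Lambda) + L(\Lambda_{se}) + L(\Lambda_{sl})$ is positive
semi-definite and satisfies, summed per coordinate,
$\phi^\top \tilde L\,\phi = U_E + U_R$. One deliberate choice in this
package: $\Lambda$ is always built from the *effective* edge moduli
$\lambda_i + \alpha(\max(2, \deg_0, \deg_1) - 2)$, so this identity holds
for every $\alpha$, not only $\alpha = 0$, and the $\alpha$ penalty flows
into the fitting step with no special casing.

# Fitting a fixed structure

`fit_graph()` alternates two exact steps, in the manner of k-means:

1. partition the data by proximity to the embedded nodes (ties break to the
   lowest node index; points farther than $R_0$ from every node are flagged
   trimmed);
2. per coordinate, solve the sparse linear system
   $[\mathrm{diag}(n_j) + \tilde L]\,\phi = b$, where $n_j$ and $b_j$ are
   the normalized weight and weighted point sums of the non-trimmed points
   assigned to node $j$.

Each step decreases the objective, so the energy trace is non-increasing —
an invariant asserted by the test suite to $10^{-9}$ relative tolerance.
Trimmed points contribute the constant $R_0^2$ to the *reported* energy but
never enter the linear system; they may re-enter at later iterations as the
graph grows towards them, which is what lets the method crawl through noisy
data from a dense seed region. The system is solved by a deterministic
sparse Cholesky factorization (`Matrix`). Nearest-node search is exact brute
force; point weights are supported throughout, so a pre-clustering
acceleration (fit centroids weighted by cluster sizes) composes with every
other feature.

Convergence is declared when the largest node displacement falls below
`eps` times the diagonal of the data bounding box (default
`eps = 1e-3`, at most 200 iterations). Normalizing by the data scale makes
the tolerance meaningful across datasets of any units; whether to normalize
at all was an open choice and is documented here.

# Learning the topology

`learn_graph()` performs a gradient-descent-like search in the space of
graph structures. From a small initial graph, each step applies every
operation of the current grammar set to every admissible element, giving a
set of candidate graphs with updated embeddings; each candidate is
re-optimized by a short warm-started fit (10 iterations by default), the
candidate with the smallest total energy $\bar U$ wins (ties keep the
earliest candidate in enumeration order), and the winner is refitted with
the full budget. Steps repeat, cycling through the schedule, until the node
budget is reached. Here $\bar U$ is the full trimmed energy including the
$\alpha$ surcharge; the structure-selection energy is kept separate from the
fitting energy in the code so that additional structural penalties can be
added later.

The four grammar operations, with their exact elasticity bookkeeping, are:

* **bisect an edge** — replace $\{A, B\}$ by $\{A, C\}, \{C, B\}$; both
  half-edges inherit $\lambda_{AB}$; $C$ starts at the midpoint. The rule
  text fixes only edge moduli, so the new 2-star centre $C$ receives the
  global default $\mu$ (matching the uniform-$\mu$ usage elsewhere).
* **add a node to a node** — leaf case: extrapolate the terminal edge
  ($C = 2\phi(A) - \phi(\text{neighbour})$), copy the terminal edge
  $\lambda$ and the neighbour star's $\mu$ (a predefined default for a
  single-edge graph); internal case: the new edge takes the mean $\lambda$
  of the star, $\mu_A$ is unchanged, and $C$ starts at the mean of the
  points assigned to $A$. When $A$ has no assigned points that mean is
  undefined; $C$ is then nudged off $A$ along its least-stretched incident
  edge.
* **remove a leaf** — delete the leaf and its edge; a neighbour reduced to
  degree 1 has its $\mu$ zeroed.
* **shrink an internal edge** — merge $A$ into $B$ at the midpoint,
  averaging the star moduli. Shrinking inside a cycle can create duplicate
  edges; they collapse to a single edge keeping the *largest* $\lambda$
  (conservative stiffness), a choice the rule text leaves open.

Mode presets: **curve** grows a path with `{bisect}` from a 2-node
first-principal-component segment; **circle** grows from a 4-node ring with
`{bisect}` (which provably preserves the single cycle); **tree** alternates
two growing steps `{bisect, add node}` with one shrinking step
`{remove leaf, shrink edge}` — one node net per cycle, with the shrink step
giving the search the chance to roll back unprofitable branches.

The reduced search (`max_candidates = k`) restricts bisection to the $k$
longest edges and node addition to the $k$ most loaded nodes — the elements
whose modification moves the energy most — with deterministic index
tie-breaks. Shrinking operations are never restricted. At the default node
budget $\lceil\sqrt{N}\rceil$ the candidate sets rarely exceed $k = 20$, so
the reduced and exhaustive searches coincide on most steps and their final
energies and star counts agree closely; the acceptance script measures
exactly this on twenty generated branching datasets.

Initializations: `pc1` (default), `density` (two neighbouring points in the
densest region — the right choice with finite $R_0$), and `mst` (k-means
centroids joined by their minimum spanning tree). `suggest_trimming_radius()`
returns the median pairwise distance on a subsample as an $R_0$ starting
guess; a density-based radius heuristic has no settled formula and is not
provided. `learn_forest()` builds disconnected approximations by re-running
the robust fit on the points left uncovered, which handles well-separated
clusters.

# Parameters that matter

| parameter | default | units | effect |
|---|---|---|---|
| `lambda` | 0.01 | dimensionless | total edge length and uniformity of edge lengths |
| `mu` | 0.1 | dimensionless | stiffness of stars; piece-wise linearity of branches |
| `alpha` | 0 | dimensionless | surcharge per edge at stars of order $k > 2$; ~0.01 discourages, ~1 forbids branching |
| `trimming_radius` | `Inf` | data units | radius beyond which points are invisible per iteration |
| `n_nodes` | $\lceil\sqrt{N}\rceil$ | count | resolution of the skeleton |

`mu` should stay roughly one order of magnitude above `lambda`. Both are
dimensionless in the sense that they do not need retuning when the data is
rescaled isotropically. An 11-node chain of unit edges has $U_E = 10\lambda$;
giving it a single degree-3 star adds $3\alpha$, two non-adjacent degree-3
stars $6\alpha$, one degree-4 star $8\alpha$ — the unit tests pin these
worked values exactly.

# Ensembles, consensus, and branching confidence

`fit_ensemble()` refits the graph on `k` subsamples of `p·N` points drawn
without replacement (member seeds derive from one master seed, making the
ensemble a pure function of its inputs). `build_consensus()` summarizes an
ensemble in five steps: pool member nodes; cluster them (average-linkage,
cut at *half* the median member edge length); drop clusters with fewer than
`min_nodes_per_cluster` members; connect cluster pairs aggregating at least
`min_edge_support` member edges; drop isolated nodes; and delete consensus
edges shorter than 0.1× or longer than 3× the median consensus edge length,
skipping any deletion that would disconnect a component. The consensus can
contain emergent topology — two tree-shaped members bracketing a ring close
into a cycle that neither member has — and the test suite constructs exactly
that case.

Numeric defaults the consensus needed but the procedure description leaves
open: `min_nodes_per_cluster = max(2, ceil(0.25 k))` and
`min_edge_support = ceil(0.25 k)`. The clustering cut is *half* the median
member edge length rather than the median itself: at the full median,
average-linkage also merges adjacent nodes *within* one member (their
spacing is exactly the median on a uniform graph), which would contract an
ensemble of identical paths instead of returning the path unchanged.

`branching_confidence()` matches member branching points (degree ≥ 3) to
their nearest reference branching point within a threshold (default twice
the median reference edge length), projects the matches onto the reference
graph, and reports the 2.5–97.5 percentile interval of their path coordinate
plus the fraction of members contributing a match.

# Projection, pseudotime, branches

`project_points()` projects every point orthogonally onto its best edge
segment (parameter clamped to $[0,1]$, ties to the lowest edge index).
`pseudotime()` is the geodesic distance along embedded edges from a root
node (default: the lowest-index leaf) to the projection, taking the cheaper
of the two edge orientations — on a cycle this resolves the antipodal
ambiguity, and on a disconnected forest each component is measured from its
own root with the component id reported. `decompose_branches()` splits the
graph at nodes of degree ≠ 2; `explained_variance()` reports FVE (variance
explained by nearest nodes) and FVEP (by edge projections), with
FVE ≤ FVEP always.

# Synthetic data

The generators are first-class, seeded, and return ground truth:

* `generate_branching()` — parabolic arcs in the unit hypercube, each new
  arc rooted at a uniformly drawn arc-length point of a previous arc in a
  random direction; points are arc-length-uniform with isotropic Gaussian
  noise, clipped to the cube. Each arc lives in a random 2D subspace of
  $\mathbb{R}^m$, so branches can extrude into dimensions that a planar
  projection collapses. Arc lengths are drawn uniformly in [0.25, 0.6] of
  the cube side — a value the construction needed but no reference fixes.
  Defaults (300 points, 3 dimensions, 4 branches, $\sigma = 0.02$) are the
  conditions under which the exact-vs-reduced comparison is run.
* `generate_armed_star()` — arms at even angles from a common centre with
  mild bending: exactly one junction of known degree, used for the
  topology-recovery checks.
* `add_background_noise()` — uniform points over the bounding box at a
  stated fraction of the output.
* `generate_circle_branch()` and `generate_intersecting_curves()` — the
  circle-plus-branch and crossing-threads ("travel maze") settings; the
  maze family is fixed so that at least two crossings are guaranteed.

What the generators do *not* emulate: single-cell count noise, dropout,
batch structure, varying local dimension, or density gradients along
branches. Passing the recovery tests shows the algorithms behave correctly
on geometrically faithful caricatures, not that any particular biological
pipeline will succeed end to end.

# Numerical choices and degenerate inputs

* Ties in partitioning and candidate selection always resolve to the lowest
  index, making every run reproducible bit for bit given a seed.
* A candidate embedding system is singular only when a connected component
  of the graph has zero non-trimmed load; this raises an informative error
  rather than a silent pseudo-inverse.
* PSD checks of $\tilde L$ use tolerance $10^{-10}$ relative to the largest
  eigenvalue; a single-node graph has zero elastic energy by definition.
* `eps` convergence is relative to the bounding-box diagonal; degenerate
  (zero-diameter) data fall back to an absolute scale of 1.
* Removing a leaf from a 2-node graph is excluded from candidate
  generation (a one-node graph cannot grow back with bisection).

# Problem sizes

The default checks run at deliberately desk-sized scales: topology recovery
on 300-point clouds with 12–20 node graphs, the exact-vs-reduced comparison
on twenty 300-point branching datasets at the $\lceil\sqrt{N}\rceil = 18$
node budget, ensembles of 5 members on 200-point clouds. These sizes were
chosen so that the full behavior — growth, shrinkage, trimming, consensus —
is exercised in minutes on one core; the algorithms themselves scale as
$O(N m s)$ per fit and $O(N m s^3)$ for a full exhaustive growth to $s$
nodes, with the reduced search dropping one factor of $s$.

# Known limitations

* Only local grammars are implemented; topologies that require distant
  rewiring (e.g., closing a specific long-range loop) can only emerge via
  the consensus mechanism, not in a single fit.
* The trimmed fit is a local optimizer: a collapsed initialization (all
  nodes in one point of a symmetric cloud) can stall in a degenerate
  stationary configuration. The provided initializations avoid this in
  practice.
* Sequential trimmed curve fits separate intersecting threads only when
  crossings are clearly transversal; near-tangent crossings can make the
  growing tip switch threads.
* Non-primitive elastic graphs (for grid-shaped manifold approximation) and
  piece-wise-quadratic robust error potentials are out of scope.
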