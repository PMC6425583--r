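---
title: "Partition-based graph abstraction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based graph abstraction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagar)
```

Single-cell expression data is commonly represented as a k-nearest-neighbor
(kNN) graph over cells. That graph is noisy and huge, which makes two basic
questions hard to answer directly: which groups of cells are genuinely
connected (possible biological transitions), and which are disconnected
(distinct populations)? `pagar` abstracts the cell graph into a small graph
over cell groups whose edge weights are a statistical measure of
connectivity, yielding a denoised, topology-preserving map that works
whether or not the data form a connected manifold. This vignette explains
the models and the choices behind them.

## The cell graph

Cells are reduced to principal-component coordinates (after the standard
count workup: total-count normalization to the median cell total, log1p,
selection of highly variable genes by binned normalized dispersion,
z-scaling clipped at |z| = 10) and connected to their `k` exact Euclidean
nearest neighbors; the directed relations are union-symmetrized. Edge
weights come from one of three kernels:

* `exponential` (default): the smooth-kNN weighting used by the UMAP
  family. For each cell the distance to its nearest neighbor is subtracted
  (local connectivity 1) and a per-cell bandwidth is solved by bisection so
  the weights sum to `log2(k)`. When the two directions of an edge
  disagree, the larger weight wins, keeping every weight a function of
  distance alone.
* `adaptive_gaussian`: a diffusion-map style kernel
  `exp(-d^2 / (s_i^2 + s_j^2))` with per-cell bandwidth `s_i` equal to the
  distance to the `ceiling(k/2)`-th neighbor. The precise bandwidth rule of
  the diffusion-pseudotime literature is not uniquely fixed; this is the
  package's declared convention and it is configurable.
* `unit`: weight 1, for purely topological analyses.

Search is exact (full pairwise distances) with distance ties broken by
lowest cell index, so results are deterministic and reproducible; this is
practical to a few tens of thousands of cells, which covers the intended
desk scale. Defaults: `k = 15`, 10 components, chosen once as standard
practice for data of a few hundred to a few thousand cells.

## The connectivity statistic

Groups come from Louvain community detection at a user-chosen resolution
(default 1.0; the resolution is deliberately a first-class parameter, not a
tuned constant), or from any external labeling. Groups that come out
internally disconnected are split into their connected components, since a
group is meant to be a set of *connected* cells.

For groups $i, j$ with $e_{ij}$ observed inter-edges, connectivity is

$$\theta_{ij} = \min\!\left(1,\; e_{ij} / \hat e_{ij}\right),$$

the ratio of observed to expected inter-edges under random assignment of
edge endpoints, capped at 1 so it reads as a confidence. The default null
sends each of the $k\,n_i$ edge endpoints rooted in group $i$ to a uniform
partner among the other cells *of its connected component*:

$$\hat e_{ij} = k \sum_c \frac{n_i^c\, n_j^c}{n_c - 1},$$

where $n_g^c$ counts group-$g$ cells in component $c$ of size $n_c$. On a
connected graph this is exactly the classic $k\,n_i n_j/(n-1)$. The
component conditioning matters for the method's central promise: a
disconnected cluster contributes no candidate endpoints to the rest of the
graph, so adding or removing it leaves every other $\theta$ entry
bit-identical — without it, the global $n$ in the denominator rescales all
uncapped entries whenever unrelated cells are added. A second built-in
null conditions on realized per-group degrees
($\hat e_{ij} = \sum_c (d_i^c n_j^c + d_j^c n_i^c)/(2(n_c-1))$) for
sensitivity analysis, and the null is pluggable (any function of the counts
object and `k`).

Edges with $\theta$ below a threshold (default 0.01, exposed everywhere)
are discarded as spurious. Counting is unweighted by default — the
statistic is about topology — with weighted counting behind a flag. The
maximum-confidence tree (minimum spanning forest under edge weight
$1/\theta$, lexicographic tie-break for determinism) summarizes tree-like
parts of the abstraction.

For a directed cell-level transition graph (e.g. from RNA velocity,
consumed as an edge list; computing velocity itself is out of scope), the
group-level transition tendency is the net flow ratio
$t_{ij} = (f_{ij} - f_{ji})/(f_{ij} + f_{ji})$ over arrow counts $f$,
antisymmetric in $[-1, 1]$. Its sign orients the undirected edges; its
magnitude is the confidence of the orientation. Undirected $\theta$ remains
the edge-existence criterion — arrows orient, they do not create edges.
Note the estimator's resolution: under symmetric noise $t_{ij}$ fluctuates
with standard deviation $\approx 1/\sqrt{f_{ij}+f_{ji}}$, so a tendency can
only be distinguished from zero at a scale set by the number of arrows
between the two groups (a few hundred arrows resolve tendencies of ~0.1).

## Pseudotime on disconnected graphs

The transition matrix applies the density correction of diffusion maps
(kernel divided by the degree product, the $\alpha = 1$ convention, exposed
as a flag) and row-normalizes. Distances from a root cell are Euclidean
distances between rows of the accumulated transition operator
$M = \sum_l \frac{\lambda_l}{1-\lambda_l}\,\phi_l\phi_l^\top$, computed in
the symmetric conjugate eigenbasis. The unit eigenspace — whose dimension
equals the number of connected components — is excluded entirely, and cells
outside the root's component are assigned `Inf` explicitly (serialized as
`"inf"`; comparisons with finite values behave as expected). Eigenvalues
close to but below 1 are reported, since they flag weakly connected
structure. On bipartite graphs the eigenvalue $-1$ modes are excluded too:
the accumulated series diverges there, and keeping the analytically
continued value produces small rank inversions at path ends. By default the
10 leading non-unit eigenpairs are used (`n_comps = Inf` gives the full
spectrum; truncation alters distances only at small scales).

Tracing gene change along a path of connected groups concatenates the
groups in path order and sorts cells within each group by their distance
from the root; a sliding-window mean (width `max(5, n/50)`, a display
convention) smooths each gene's profile. Paths through groups the root
cannot reach are rejected rather than silently misordered. Branch-point
detection within pseudotime is deliberately absent — paths in the
abstracted graph replace it.

A practical note on exactness: even on noise-free single-trajectory data,
diffusion distances order cells *almost* but not exactly by arc length when
cells are sampled non-uniformly — random-walk geometry responds to local
sampling-density clumps, so a few adjacent ranks swap (rank correlation
0.998–0.999 in the package's checks, identical behavior in independent
implementations of the same construction). Tests therefore pin the rank
correlation, not exact order.

## Embeddings that preserve topology

The abstracted graph is small, so a force-directed layout of it is
essentially free. Single-cell embeddings are initialized from that coarse
layout: the members of each group are placed uniformly at random in an
axis-aligned square centered on their group's position with half-edge equal
to half the distance to the nearest other group. The distance is measured
in the Chebyshev (L-infinity) metric — squares are balls of that metric, so
non-overlap of the rectangles is guaranteed by construction; with Euclidean
distances two squares can still overlap diagonally. Conversely, a coarse
layout is read off a fine one by coordinate-wise medians, which for
rectangle-initialized layouts lands within the half-edge of the original
positions. Refinement of the initialized embedding uses a standard
Fruchterman–Reingold iteration on the cell graph (via igraph, attraction
weighted by the kernel weights), with a lightweight attraction/repulsion
alternative (`umap_like`); `n_iter = 0` returns the initialization
unchanged, and every stage is deterministic given its seed. Layouts are
2-D, matching how such maps are consumed.

## Evaluation measures

**Geodesic divergence (KL_geo).** Faithfulness of an embedding to global
topology is scored by comparing shortest-path distances along the graph in
the high-dimensional space against those in a kNN graph built on the
embedding, over one shared random cell sample. Edge length is
`1 - log(weight)` — 1 for a perfect-similarity edge and monotone increasing
as similarity decays; a plain `-log` variant exists but assigns length 0 to
weight-1 edges, which collapses hop structure on unit-kernel graphs. The
two distance vectors (over pairs finite in both spaces) are normalized to
distributions $P$ (high-dimensional) and $Q$ (embedding) and scored by
$D_{KL}(P\|Q)$; normalization makes the measure scale-invariant, so
identical or uniformly scaled embeddings score exactly 0. A Gaussian-kernel
transform of the distances (bandwidth = median distance) and a symmetrized
divergence are available behind switches, since the exact transform is a
modeling choice.

**Path-set topology score.** Two abstractions of the same cells are
compared through their path sets: for every pair of leaf nodes (degree
$\le 1$) in the reference, the shortest path is computed in both graphs and
checked step-by-step. Because one graph's groups can straddle several of
the other's, each node is associated with *every* node of the other graph
it shares cells with, ranked by the smaller of the two relative overlaps;
the longer path is translated into these association sets and the shorter
path must step through them in order. A pair disconnected in both graphs is
consistent; disconnected in exactly one, inconsistent. The score is the
fraction of consistent leaf pairs. Within an abstracted graph, shortest
paths are weighted by inverse connectivity — paths follow high-confidence
edges — which stops a barely-above-threshold spurious edge from rerouting a
path and misreporting the topology. A single-majority-mapping variant of
this measure was evaluated and rejected: it scores a topologically perfect
branching abstraction as wrong whenever the branch-point group overlaps
several true segments, which is the typical case.

## The simulator

Ground truth comes from piecewise-linear expression manifolds: a segment
graph (chain, one branch point, two branch points, forests) where each
segment is a line in gene space with a random direction vector, continuous
at branch points. `segment_length` (default 1) is the per-gene scale of one
segment's expression change, i.e. each gene ramps by O(segment_length)
along a segment; the default noise, `0.3 * segment_length` per gene, makes
noise 30% of a gene's dynamic range. (Scaling noise instead to the total
gene-space arc length would multiply the per-gene noise by the square root
of the gene count and destroy all recoverable structure at any parameter
setting — not a usable reading for a benchmark generator.) Cells are
sampled uniformly along segments (200 per segment, 50 genes by default, so
Louvain at resolution 1 yields several groups per segment and the
abstraction is exercised nontrivially); distinct trees of a forest are
placed far apart; a disconnected cluster can be appended at a configurable
offset (default 10x the manifold diameter, far enough that no kNN edge can
cross). Velocity ground truth emits one arrow per directed kNN relation,
oriented along true time and flipped with a configurable rate. Values are
continuous (post-preprocessing scale) by default; a Poisson emission mode
exercises the count-preprocessing path.

What the simulator does *not* emulate: library-size variation, dropout,
batch effects, curved manifolds (a spline option would add curvature but
segments are straight lines by default), or realistic gene-gene
correlation. Tests passing on these data show that the statistic, the
pseudotime extension and the embedding contracts behave as designed on
clean topologies — not that any particular biological dataset will be
recovered.

## Numerical and design notes

* Determinism throughout: exact kNN with index tie-breaks, seeded Louvain,
  seeded layouts and sampling, lexicographic MST tie-breaks. Rerunning a
  configuration reproduces byte-identical artifacts.
* Degenerate inputs: all-zero count matrices fail with an explicit
  "empty after filtering" error; isolated graph nodes become absorbing
  self-loops (flagged); a single coarse node falls back to a unit
  rectangle half-edge with a warning; a null that expects zero edges where
  edges are observed yields connectivity 1 with a warning.
* Problem sizes in the shipped checks were picked to exercise the claims
  meaningfully at desk scale: 1000 random small graphs against the
  brute-force oracle, 20-seed recovery runs on 600–1000-cell trees, a
  5-resolution x 4-seed robustness sweep, 10-seed paired embedding
  comparisons.
* The benchmark harness quantifies the method's robustness claim
  concretely: across a Louvain resolution sweep the abstracted topologies
  agree with each other (and with ground truth) more than the partitions
  themselves do, measured by the path-set score versus adjusted mutual
  information (implemented here under the permutation-model expectation
  with arithmetic normalization, as no installed package provides it).

## Limitations

Exact neighbor search is quadratic in cells; an approximate backend is an
interface away but out of scope. The abstraction inherits the partition:
pathological labelings (groups mixing disconnected cells) are handled but
not meaningful. The directed tendency consumes an externally computed
velocity graph and inherits its biases. Convergence-speed comparisons
against external embedding engines depend on those engines' cost functions
and are not attempted here.
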