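---
title: "Finding overlapping and bridging nodes with circuit flows"
author: "CircuitKeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding overlapping and bridging nodes with circuit flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircuitKeys)
```

## The problem

Networks with community structure — social groups, collaboration networks,
neural circuits — are held together by a small number of *connector* nodes.
Two kinds matter: **overlapping nodes**, which genuinely belong to two or
more communities and hold a number of edges into each, and **bridging
nodes**, which sit inside one community but own the few edges that reach
across to another. Both control communication between communities, yet
finding them usually requires first partitioning the network into
communities — a problem that is itself ill-posed precisely when overlapping
nodes exist.

CircuitKeys identifies and distinguishes both kinds without any community
partition, by treating the network as an electrical circuit.

## The circuit model

**Undirected networks.** Every edge $(i,j)$ becomes a resistor with
conductance $c_{ij}$ (default 1; supplied per edge if the data carry
weights). For a chosen source $s$ and target $t$, a unit current is injected
at $s$ and removed at $t$. Ohm's law gives the current on an edge as
$I_{ij} = c_{ij}(V_i - V_j)$, and Kirchhoff's current law at every other
node makes each voltage the conductance-weighted average of its neighbours'
voltages. This is a sparse linear system in $V$: the package grounds the
target and solves the reduced conductance-Laplacian system directly
(`method = "direct"`), or iterates the neighbour-average fixed point
(`method = "jacobi"`), which converges for any connected network because the
grounded iteration matrix is substochastic.

Because the current entering a node equals the current leaving it, the
current *through* an interior node is half the sum of the absolute currents
on its incident edges,
$$F_i(s,t) = \tfrac12 \sum_j |I_{ij}(s,t)|,$$
while the two endpoints are fixed at the injected current,
$F_s = F_t = 1$. (At an endpoint the natural half-sum is exactly $1/2$ — the
endpoint is the potential extremum, so all its incident currents point the
same way — and the implementation exploits that identity to accumulate the
full sweep from the per-edge totals.) The **current-flow centrality** is the
average over all $M = N(N-1)/2$ unordered source–target pairs:
$$C_i = \frac{1}{M}\sum_{\{s,t\}} F_i(s,t).$$
The endpoint convention and the pair normalization were calibrated against
the published worked example that ships as the `twogroup13` fixture: with
$F_s = F_t = 1$ and unordered pairs, the package reproduces the printed
centrality column to all three printed decimals (see
`tests/testthat/test-acceptance.R`), and no alternative convention we tried
does.

**Directed networks.** Each arc becomes an *ideal diode* in series with its
conductance: it conducts (with conductance $c_{ij}$) only while
$V_i > V_j$, and blocks otherwise; ties carry zero current. Every node is
additionally attached to a universal ground held at $0$ V through a branch
of conductance $g$ (`groundConductance`, default 1), and each node in turn
serves as the source of a unit current; the injected current leaves through
the ground branches. The directed centrality averages the throughflow over
the $N$ source configurations, counting a node's ground branch among its
incident edges (otherwise Kirchhoff's law at that node would not halve
correctly).

The diode constraint makes the system piecewise linear. The default solver
alternates exact sparse solves of the symmetric
Laplacian-plus-ground system restricted to the currently conducting diode
set with updates of that set; each candidate set gives a symmetric positive
definite system, and the iteration stops when the conducting set reproduces
itself. This is exact and fast, and on every test instance it terminates in
a handful of set updates. A damped Jacobi relaxation
(`method = "relaxation"`, damping 0.5) is retained both as a cross-check
and as the fallback if the set ever cycles; damping is necessary because
diode switching makes the undamped fixed-point map discontinuous. Both
schemes are validated against an exhaustive enumeration of all $2^E$ diode
on/off states on small instances.

Two modelling choices are not forced by the physics and are exposed as
configuration: the ground-branch conductance (no canonical value exists;
1.0 treats the ground like an ordinary edge) and the source convention
(constant *current* injection, chosen for consistency with the undirected
definition of $C$; a constant-potential source would rescale each
configuration by its input resistance).

## Telling the two kinds apart: the imbalance index

Summing $|I_{ij}|$ over the full configuration sweep gives each edge an
accumulated flow $T_{ij}$ (for directed networks, opposite arcs are merged
by adding their accumulated currents). A bridging node funnels essentially
all of its cross-community current through its one bridging edge, so one
incident $T$ value towers over the rest; an overlapping node spreads the
same traffic over its many edges into each community. The **imbalance
index** captures this:
$$D_i = \max_j T_{ij} - \operatorname{median}_j T_{ij},$$
with the median over the node's incident edges (an even count averages the
two middle values; nodes of degree $\le 1$ get $D_i = 0$). Values are
normalized by the single global maximum — per-community normalization would
require the very partition the method avoids. Whether a directed node's
ground branch participates in its $D$ is configurable
(`includeGroundInD`); the default excludes it so that $D$ reflects network
edges only.

## Selection and classification

Key nodes are the top fraction $q$ (default 10%) of nodes by $C$: the
threshold is the score at rank $\lfloor qN \rfloor$ of the empirical score
distribution — computed by rank, not interpolation, so the threshold is
attained by an actual node — and nodes numerically tied with the last
selected score are all included, favouring recall of connectors. If every
node scores identically (e.g. a single complete community) no node is
distinguishable and the key set is empty, with a warning.

Among key nodes, normalized $D \ge$ `dThreshold` (default 0.5) classifies a
node as bridging, otherwise overlapping. No principled universal threshold
exists — the underlying difficulty is that communities themselves have no
exact definition — so the cut is a declared heuristic, and a 2-means split
of the key nodes' $D$ values is available as an alternative rule
(`dRule = "kmeans2"`).

## What the bundled networks show

* `twogroup13` — two mirrored 6-node groups whose gateways (6, 8) are
  joined both directly and through the central connector 7. The direct
  gateway edge removes node 7 from every shortest path, so its betweenness
  is exactly 0, while all electrical paths between the groups load it:
  $C_7 = 0.308$ beats the mid-group quartet's $0.279$. This is the
  quantitative anchor of the test suite. The topology was reconstructed by
  exhaustive search over all mirrored within-group edge sets against the
  published betweenness column; exactly one topology class matches, and it
  then reproduces the published centrality column with no further freedom.
* `schematic32` — a synthetic three-community schematic (the file name
  marks it as synthetic: it was built from a fixed seed to embody the
  documented structure, not transcribed from a published drawing) in which
  node 12 overlaps two communities and hubs 16 and 24 each own one bridging
  edge. The analysis selects exactly {12, 16, 24} and classifies 12 as
  overlapping, 16 and 24 as bridging.
* `zachary` — the karate-club social network, unweighted. The top three
  nodes by $C$ are the instructor (1), the administrator (34) and node 3;
  at the default threshold the first two classify as bridging and node 3 as
  overlapping, matching the standard reading of that network's split.

## The synthetic benchmark generators

`generateTwoGroupToy()` scales the two-group construction to any group
size; the connector's betweenness is zero by construction at every size.

`generatePlantedNetwork()` emulates a modular network with planted
connectors: dense Erdős–Rényi community blocks ($p_\text{in} = 0.3$, four
communities of 25 by default), bridging nodes that are ordinary members
plus exactly `bridgingOutDegree` (2) cross edges, and overlapping nodes
wired with `overlapDegreePerCommunity` (4) edges into each of two host
communities. The background cross-community edge probability `pOut`
defaults to **0**: the regime the generator emulates is one in which the
communities are connected *only through the connectors*, which is exactly
what makes "connector" a meaningful ground-truth label. With background
cross edges at even 1% density, a 100-node instance carries ~37 random
inter-community edges that collectively out-conduct 3 planted connectors,
and the planted labels stop describing the actual conduits; users wanting
noisy regimes can raise `pOut` (kept below `pIn`) and should expect recall
to degrade accordingly. Generation is seeded and retried until connected
(when any cross mechanism exists; with none, the disconnected community
partition is the legitimate result).

`generateLfrLike()` produces degree heterogeneity in the LFR style:
degrees from a truncated discrete power law (exponent `tau1 = 2`, support
$[2, \sqrt n]$ — the truncation keeps desk-scale instances realizable and
connected), community sizes from a second power law (`tau2 = 1`), and a
mixing fraction `mu = 0.1` of each node's stubs crossing communities, with
uniform stub matching and rejection of self-loops and multi-edges (stubs
unmatched after bounded retries are dropped, perturbing realized degrees
only slightly). These parameter defaults are the LFR literature's customary
values, declared here as repository defaults. The generator reproduces the
statistical *shape* such benchmarks rely on, not any reference
implementation bit-for-bit; overlapping-membership LFR variants are out of
scope.

What passing tests on these generators does and does not show: the planted
generator produces idealized, sharply separated communities with exact
planted cross degrees, so recovery there demonstrates the method's
mechanics (current concentrates on the true conduits; $D$ separates one-hot
from balanced flow patterns), not performance on noisy real data, where
community borders blur and the 10% cut and 0.5 split are at best
reasonable defaults.

## Numerical choices

* Default solver tolerance $10^{-10}$ (relative to the injected current),
  iteration cap $10^5$; the direct sparse solve is default, Jacobi retained
  for cross-validation.
* The full-sweep centrality uses one dense grounded inverse of the
  conductance Laplacian per component and accumulates per-edge responses
  over pairs, $O(E N^2)$ after an $O(N^3)$ factorization — exact, and
  comfortably fast to a few thousand nodes. Test problem sizes: oracle
  equivalence on 100 random graphs of up to 8 nodes (brute-force
  pseudoinverse loop) and exhaustive $2^E$ diode enumeration up to 12 arcs;
  the planted-recovery study uses 50 seeded replicates of the ~100-node
  default generator.
* Parallel edges merge by conductance addition (exact for resistors);
  self-loops are rejected (they carry no current and break the adjacency
  invariants).
* Numerically tied centrality scores (automorphic orbits computed in
  floating point) are treated as ties at the selection threshold at a
  relative tolerance of $10^{-9}$.
* Disconnected undirected input is handled per component; source–target
  pairs never span components. The top-$q$ selection is global by default,
  not per component.

## Limitations

* The method ranks and separates connector *candidates*; the 10% / 0.5
  thresholds are declared heuristics, configurable but not adaptive.
* Directed analysis depends mildly on the ground conductance $g$; there is
  no canonical value, and rankings (not exact scores) are the robust
  output.
* The pair sweep is exact, not sampled; beyond a few thousand nodes the
  dense per-component inverse becomes the bottleneck.
* Ideal diodes have no forward voltage drop, and complex impedances are
  out of scope.
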