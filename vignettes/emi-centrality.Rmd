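---
title: "Entropy and mutual-information node importance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy and mutual-information node importance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eminet)
```

## The problem

Which nodes matter most in a network? Degree counts only immediate
neighbors; closeness and betweenness need global shortest paths; k-shell
collapses many nodes into few coarse layers. The EMI score implemented here
takes a middle road: it looks one ring further out than degree — at the
*distribution* of the neighbors' degrees and strengths — and then corrects
for a failure mode shared by most local scores, the double-counting of
influence between adjacent nodes whose neighborhoods largely coincide.

## The score

For a node $v$ with neighbor set $N_v$ (neighbors are direction-agnostic:
any edge between two nodes makes them neighbors), the **structural entropy**
is the Shannon entropy of the neighbors' degree distribution. On a directed
network it splits into in- and out-components,

$$S_v^{\mathrm{in}} = -\sum_{j \in N_v} \frac{d_j^{\mathrm{in}}}{\sum_{k \in N_v} d_k^{\mathrm{in}}}
  \log_{10} \frac{d_j^{\mathrm{in}}}{\sum_{k \in N_v} d_k^{\mathrm{in}}},
  \qquad S_v = S_v^{\mathrm{in}} + S_v^{\mathrm{out}},$$

and on an undirected network it is a single entropy over the neighbor
degrees. The **interactive entropy** $I_v$ is the same construction applied
to the neighbors' strengths (inbound/outbound edge-weight sums); it exists
only on weighted networks — with unit weights it would duplicate $S_v$
exactly, an identity the test suite asserts.

The **mutual power** penalises redundancy. For each neighbor $j$, with
$F$ denoting set size and $N_{vj} = N_v \cap N_j$,

$$MI_v = \sum_{j \in N_v} \frac{F(N_{vj})}{F(N_v)+F(N_j)}
  \log_{10} \frac{F(N_v)+F(N_j)-F(N_{vj})}{F(N_v)+F(N_j)} \;\le\; 0,$$

with equality exactly when $v$ shares no neighbor with any of its
neighbors. Each term is the (joint-mass weighted) log of how much the
combined audience shrinks once the overlap is removed, so two adjacent hubs
serving the same leaves each pay for the duplication.

The overall importance is

$$K_v = S_v + I_v + MI_v \quad \text{(weighted)}, \qquad
  K_v = S_v + MI_v \quad \text{(unweighted)},$$

and nodes are ranked by decreasing $K$, ties broken by node identifier so
output files are reproducible byte for byte.

### Worked example

The built-in four-node fixture (`toy_network()`: a→b weight 1, a→d 4,
b→c 2, c→a 3) exercises every branch:

```{r toy}
fit <- emi(toy_network())
fit
```

Node *a*'s components decompose as $S_a = \log_{10} 3 + \log_{10} 2$
(neighbor in-degrees $\{1,1,1\}$, out-degrees $\{1,1,0\}$ — node *d* has
out-degree 0 and contributes nothing, the $0 \log 0 := 0$ convention) and
$MI_a = 2 \cdot \tfrac15 \log_{10}\tfrac45$ from the two neighbor pairs
that share one common node each.

## Choices that were genuinely open

**Logarithm base.** Base 10 everywhere, configurable through
`emi_config(log_base=)`. Entropies scale by a constant across bases, so
rankings are base-invariant; only the printed magnitudes change.

**The joint set in $MI$.** The combined neighborhood size
$F(N(v,j))$ is read as the *sum* $F(N_v) + F(N_j)$ (a multiset
combination), not the size of the set union — only this reading reproduces
the fixture's penalty values. Likewise the double sum over common
neighbors is collapsed to one term per neighbor pair, which keeps the
joint mass a probability; the alternative reading that repeats each term
$F(N_{vj})^2$ times coincides with the default whenever pairs share at
most one node and is exposed as `emi_config(mi_terms = "common-squared")`
for sensitivity analysis.

**Single-neighbor nodes.** Strictly, a node with one neighbor has
singleton entropy multisets and scores 0. The compatibility rule
(`compat_single_neighbor = TRUE`) additionally includes the node's own
degree and strength in the multisets, giving leaves a small positive
score. Strict is the default; both are tested and neither is treated as
canonical.

**Negative weights.** The entropy construction needs positive weights.
Loaders shift by $w' = w - \min(w) + 1$ when any weight is non-positive
(rating scales routinely include negative values); the shift is monotone,
so strength *orderings* are preserved while the entropy becomes well
defined. It is switchable off, in which case loading fails loudly.

**Isolated nodes** score $K = 0$ with a warning rather than erroring, so
whole-network rankings never abort. **Self-loops** are dropped at load
time: every formula ranges over neighbor sets that exclude the node
itself. **Parallel edges** merge by weight summation, collapsing
multigraph inputs to one weight per ordered pair.

## Comparator centralities

Degree, closeness (reciprocal farness over reachable nodes, 0 when
nothing is reachable), k-shell (total degree on directed networks),
betweenness (normalised by $(n-1)(n-2)$, halved for undirected),
eigenvector centrality, and the textbook PageRank iteration
$PR \leftarrow A^{\!\top} PR$ with a column-normalised transition matrix,
uniform start, dangling mass redistributed uniformly, and damping off by
default (a damping factor is available). Shortest-path methods treat edge
weights as lengths by default; because many weighted networks carry
affinity-style weights (bigger = closer), `weight_as = "affinity"` uses
$1/w$ instead.

Two numerical notes. Eigenvector centrality power-iterates on $A + I$:
the spectral shift leaves eigenvectors untouched but makes the Perron
vector strictly dominant, so the iteration converges on bipartite graphs
where $\pm\lambda_1$ would otherwise make it oscillate. Convergence is
declared at a max-norm difference below `tol` between successive
unit-sum iterates, and failure to converge is an error, not a silent
partial answer.

## Ranking evaluation

`make_ranking()` groups scores into tie groups by rounding to
$-\log_{10}(\text{tol})$ decimals (default $10^{-10}$) — deterministic and
order-independent, unlike pairwise chaining, at the cost that two scores
straddling a rounding boundary may separate. The discriminability metric

$$M(R) = \left(1 - \frac{\sum_r n_r (n_r - 1)}{n (n - 1)}\right)^{\!2}$$

uses $n$ = the number of *nodes*: that is the only reading under which
all-distinct ranks give $M = 1$ and a single all-tied rank gives $M = 0$,
the two endpoints the metric is defined by. The rank-occupancy CCDF and
top-$k$ overlap (tie groups flattened deterministically) complete the
comparison toolkit; externally computed score files can be registered via
`read_node_scores()` so methods this package does not implement can join
the comparison.

## SI spreading

Seed-set influence is measured with a susceptible–infected process (no
recovery): synchronous timesteps, each infected node attempting each
susceptible out-neighbor once per step. On weighted networks the
per-contact probability is $\lambda_{ij} = (w_{ji}/w_{\max})^\alpha$
($\alpha = 1$ by default, as the exponent is a free positive constant);
on unweighted networks it is a constant $\beta$. The process runs until a
step cap (default 100) or until no susceptible node is adjacent to an
infected one — the natural stopping point, since susceptible–infected
dynamics never "finish" on their own on disconnected graphs. Each of the
`runs` repetitions (default 100) draws from an RNG stream derived as
`seed + run`, so results are bit-reproducible, methods compared through
`seed_set_experiment()` share per-run streams (variance-paired
comparison), and the caller's RNG state is never touched.

## What the generators emulate — and what they do not

`analytic_family()` (star, path, cycle, complete) pins closed-form
anchors: the star hub scores $S = \log_{10}(k)$ against its $k$
unit-degree leaves; complete graphs collapse to a single tie group with
$M(R) = 0$. `random_network()` produces Erdős–Rényi-style graphs with
optional direction and integer weights (flight-count-style; a continuous
option exists). `overlap_pair_network()` builds the canonical
over-valuation scenario: two connected hubs with a tunable shared
neighborhood. On that family the *penalty* $MI$ is strictly decreasing in
the overlap; the *total* $K$ is not monotone unless the leaves' degrees
are controlled too, because converting a private leaf into a shared one
also raises its degree and hence the hub's structural entropy — the tests
therefore check $K$ monotonicity on a degree-controlled variant.

These generators are deliberately simple: homogeneous degree
distributions, independent edges, no community structure, no degree
correlations. Passing tests on them demonstrates correctness of the
formulas and their invariants, not that EMI outperforms alternatives on
heavy-tailed real networks; for that, load real edge lists and run the
same pipeline.

## Problem sizes and test scale

The suite anchors every published value of the four-node worked example
exactly, and exercises the property-level guarantees on random networks
of 8–40 nodes (k-shell against a brute-force pruning oracle up to 30
nodes, entropy bounds, permutation equivariance), with Monte-Carlo SI
checks at 1000–1500 runs where a binomial expectation is available.
These sizes make every oracle exhaustively checkable while keeping the
whole suite in a few seconds; all operations scale to networks orders of
magnitude larger.

## Known limitations

* The rounding-based tie detection can split scores that differ by less
  than the tolerance but straddle a rounding boundary.
* The simplified PageRank iteration is run for a fixed number of sweeps
  rather than to a convergence criterion, mirroring its textbook
  definition; use the damping option for graphs where the undamped
  iteration cycles.
* Stress, radiality, bridging, centroid, eccentricity and
  maximum-neighborhood-component centralities are not implemented;
  external score files can stand in for them in evaluations.
* SI spreading uses synchronous discrete-time updates; no
  continuous-time (Gillespie) or recovery-state variants.
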