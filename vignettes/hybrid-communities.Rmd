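---
title: "Hybrid node-link communities: model, fitting, and structure selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid node-link communities: model, fitting, and structure selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlcomm)
```

## The problem

Communities in networks are classically found in one of two shapes. *Node
communities* are groups of nodes densely linked inside and sparsely linked
outside; each node belongs to one group. *Link communities* group the
links instead, and a node inherits the memberships of its adjacent links,
which lets hub-like nodes belong to several groups — at the price of
forcing *every* link into a community, so networks without overlap get
spurious overlap. Many real networks mix both situations: some parts are
clean node modules, others are genuinely relational and best described by
typed links, and some nodes or links are background that belongs nowhere.
`nlcomm` detects such *hybrid* structures: `c` communities, each
independently typed as a node community or a link community, plus
background.

## The generative model

The only parameters are expected degree allocations. For a network with
observed weighted degrees $d_i$ and total weight $m$, node $i$ assigns an
expected degree $d_{ik} \ge 0$ to each community $k$, subject to

$$\sum_{k=1}^{c} d_{ik} = d_i .$$

Each community is a degree-corrected random multigraph with no internal
structure — the same null model that underlies modularity — so inside
community $k$ the expected weight between $i$ and $j$ is
$d_{ik} d_{jk} / D_k$ with $D_k = \sum_i d_{ik}$, and the network is the
superposition

$$\hat w_{ij} = \sum_k \frac{d_{ik} d_{jk}}{D_k}.$$

With $c = 1$ this is exactly the configuration null $d_i d_j / 2m$.
Observed weights are treated as Poisson counts with means $\hat w_{ij}$
(multi-edges and self-loops allowed; the diagonal convention
$W_{ii} = 2 \times$ self-edge weight keeps every degree identity exact).
Dropping constants, the log-likelihood over ordered node pairs including
self-pairs is

$$L = \sum_{i,j} \left( w_{ij} \ln \hat w_{ij} - \hat w_{ij} \right),
\qquad 0 \ln 0 = 0,$$

and since $\sum_{ij} \hat w_{ij} = \sum_k D_k$ the subtracted mass has a
closed form. Whether the pair sum includes self-pairs only shifts $L$ by a
quantity that is constant under the allocation constraint, so no
comparison made by the package depends on that convention; we state it for
reproducibility.

## Two learners

**EM** (`fit_em()`). Jensen's inequality on $L$ introduces, for every
observed edge, a responsibility vector $q_{ij,\cdot}$ (the posterior that
the edge came from each community). The E-step is
$q_{ij,k} \propto d_{ik} d_{jk} / D_k$; the M-step maximizer under the
allocation constraints is the closed form
$d_{ik} = \sum_j w_{ij}\, q_{ij,k}$, which satisfies the constraints
*exactly* because each responsibility vector sums to one (the test suite
verifies the closed form against direct constrained numerical maximization
of the auxiliary objective). $L$ is non-decreasing along iterations.
Defaults: 10 restarts, 500 iterations, relative tolerance `1e-8`;
responsibilities are stored per edge, so one iteration costs $O(mc)$.
Communities whose column sum decays to zero stay dead — pruning the number
of communities is the job of the description-length selection, not of the
likelihood.

**Penalized symmetric NMF** (`fit_nmf()`). Replacing the Poisson
likelihood by a squared loss turns the fit into symmetric nonnegative
factorization of the weight matrix: with $X_{ik} = d_{ik}/\sqrt{D_k}$ we
have $\hat W = X X^\top$ and the objective

$$O = \lVert A - XX^\top \rVert_F^2
      + \lambda \lVert XX^\top \mathbf 1 - d \rVert^2,$$

whose second term is the degree-allocation constraint as a soft penalty.
The multiplicative update divides the negative gradient part by the
positive part and damps with exponent $\eta = 1/2$,

$$X \leftarrow X \circ
  \left(\frac{AX + \tfrac{\lambda}{2}(d\mathbf 1^\top + \mathbf 1 d^\top)X}
       {XX^\top X + \tfrac{\lambda}{2}(w\mathbf 1^\top + \mathbf 1 w^\top)X}
  \right)^{1/2}, \qquad w = XX^\top \mathbf 1 .$$

$O$ is non-increasing under this rule; the property is asserted on every
test run across a randomized battery rather than assumed, and $\eta = 1/4$
would be the fallback damping had the battery found a violation (it did
not). Entries are floored at $10^{-12}$ because a multiplicative rule
cannot leave zero. The schedule is two-phase, following the observation
that the penalty is best switched on from a good unconstrained start:
phase 1 runs $\lambda = 0$ to convergence, phase 2 restarts from that
factor with $\lambda = 1000$. The final allocation satisfies the degree
constraint to about $10^{-3}$ relative rather than exactly; `fit_em()` is
the learner of record whenever exact allocation matters.

## From parameters to structure

Soft memberships are degree shares: node $i$ belongs to community $k$ with
probability $S_i^k = d_{ik}/d_i$ (the community it devotes most of its
connectivity to), and an observed link belongs to $k$ with probability
$R_{ij}^k \propto d_{ik} d_{jk} / D_k$. Hardening is by argmax, ties to
the lowest community index so output is deterministic. A typing assigns
each community `node` or `link`: node-typed community $k$ receives the
nodes whose argmax is $k$; link-typed $k$ receives the links whose argmax
is $k$. A node whose best community is link-typed is *not* in any node
community (it may still be covered through its links); a link whose best
community is node-typed is background; zero-degree nodes are background.

**Scoring a structure.** Every typed structure induces a node cover:
node-typed communities contribute their node sets, link-typed ones the
endpoint sets of their links, and uncovered positive-degree nodes become
singleton modules. The cover is scored in bits by a two-level map
equation (`map_equation_mdl()`): stationary visit rates of an undirected
random walk are degree-proportional, each module pays an index codebook
over its members plus an exit word, and module entries pay a top-level
codebook. For overlapping covers a node's visit rate must be divided
among its modules. Two splits are implemented: proportional to the node's
edge weight into each module (default) and equal. Both reduce to the
classic two-level map equation on disjoint partitions (tested against an
independent closed-form evaluation); the proportional split is the
default because it reproduces the published description lengths of the
karate-club link cover to within 0.005 bits, where the equal split is off
by 0.07 — the disjoint core needs no calibration, and this was the only
free choice in the instantiation. No teleportation is used; flows are
weighted globally by $d_i/2m$, which handles disconnected covers.

**Choosing the types.** With $c$ communities there are $2^c$ typings.
`search_types()` enumerates them exhaustively for small $c$ (the oracle,
used up to $c = 15$) or runs a greedy descent: starting from the all-node
typing, the all-link typing, and 5 random typings, sweep communities
$1..c$ and flip any type whose flip shortens the description, until a
sweep makes no change (at most 50 sweeps). Because the pure typings are
always among the starting points, the hybrid result can never be worse
than the node scheme or the link scheme — an invariant the test suite
checks — and on every fixture we have tried the greedy result equals the
exhaustive optimum.

**Restart selection and a real degeneracy.** `detect_communities()`
returns the restart with the highest likelihood. The likelihood can have
*exactly* tied optima: in the 14-node worked example (`toy_network()`),
two 5-cliques sharing a node, a third clique, and one bridge edge, the
bridge can be absorbed by either adjacent community and every pair term
in $L$ cancels exactly (both optima score $L = -78.4729$). Restarts tied
within $10^{-6}$ relative likelihood are therefore re-ranked by the
method's own structure criterion — the map-equation description length of
their inferred structures — and only then by restart order. In the worked
example this prefers the allocation whose structure scores 2.9199 bits
over the 2.9446-bit alternative. The degeneracy is a property of the
model, not a numerical artifact; scripts that report parameter values on
this fixture stabilize them as the median over 15 replicate runs.

## Choosing the number of communities

`sweep_c()` fits every candidate $c$ in a range and returns the
description-length curve and its argmin (ties to the smaller $c$). On the
packaged fixtures the curve selects 3 communities for the karate club and
8 for the co-appearance network, matching the published sweeps. For
networks too large to sweep, `recursive_bipartition()` needs no $c$: it
repeatedly refits $c = 2$ on a part's induced subgraph and accepts the
split only if the *global* description length of the assembled partition
drops — raw likelihood always improves with more parameters, so the
MDL is the acceptance criterion — with parts below `min_size = 3` never
split. Within the recursion parts are hardened by node argmax; community
types are searched once at the end, on the degree allocation the final
partition itself induces ($d_{ik}$ = node $i$'s weight into part $k$,
which satisfies the allocation constraint exactly and avoids a full
refit).

## Evaluation metrics

- `overlapping_nmi()`: normalized mutual information extended to covers —
  modules as binary membership variables, conditional entropies minimized
  over matching modules, with the no-match guard that keeps unrelated
  modules from spuriously explaining each other. 1 iff the covers are
  identical up to module order.
- `extended_modularity()`: modularity generalized to covers by damping
  each pair by the product of the nodes' membership counts; equals
  standard modularity on partitions (cross-checked against igraph).
- `enrichment()`: mean pairwise similarity within communities (pairs
  pooled across communities, counted once per community containing both
  endpoints) over the global mean pairwise similarity; unordered pairs
  throughout — the convention cancels in the ratio.
- `rescale_mdl()`: the linear map sending a reference optimum to 1 and a
  reference baseline to 0.
- `sample_subnetwork()`: the ego sampler for large covered networks —
  dedupe ground-truth communities, drop those with $\le 2$ nodes, pick a
  random node with $\ge 2$ memberships, induce the subgraph of all nodes
  sharing a community with it, and reject samples whose ground-truth
  extended modularity is below $\varepsilon = 0.1$.

## The planted benchmark

No standard synthetic benchmark exists for hybrid structures, so
`planted_hybrid_network()` builds one from blocks: `clique` blocks are
planted node communities; `chain` blocks are cliques sharing single
nodes, planted as link communities whose shared nodes are the designed
overlap. Noise edges appear independently between blocks with probability
`p_between = 0.02` — sparse background typical of planted-partition
benchmarks; draws are rejected until every planted community keeps more
internal than boundary weight, so the planted signal is always present.
`planted_benchmark()` fixes the configuration used in the recovery study:
100 nodes, eight communities (four cliques of 12–13 nodes, two two-clique
chains), which the full pipeline recovers with overlapping NMI above 0.9
in well over 90% of simulations.

What the generator emulates is community structure with controlled
overlap and clean typing; what it does not emulate is degree
heterogeneity inside communities, weight heterogeneity, hierarchical or
nested structure, and overlap denser than single shared nodes. Passing
recovery tests on it therefore demonstrates correctness of the pipeline
on well-separated structure, not performance on hub-dominated or weakly
modular real networks.

## Numerical choices and problem sizes

- Argmax ties break to the lowest community index; sweep ties to the
  smallest $c$; restart ties as described above. All outputs are
  deterministic under a fixed seed.
- EM: restarts 10, `max_iter` 500, tol `1e-8` (relative change of $L$).
  NMF: restarts 10, `max_iter` 1000 per phase, tol `1e-8`,
  $\lambda \in \{0, 1000\}$, $\eta = 1/2$, floor `1e-12`. Empty
  communities contribute zero expected weight rather than erroring.
- The test suite works at fixture scale: the 14-node example, the 34-node
  and 77-node classics, random graphs of 4–13 nodes for the property
  batteries (100 seeded runs per learner), and 50 seeds of the 100-node
  benchmark. The 77-node co-appearance fit uses 300 restarts with
  `max_iter` 2000 and tol `1e-10`: at $c = 8$ its likelihood surface is
  rugged and the published description lengths correspond to the global
  likelihood optimum, which lighter settings miss. The co-appearance
  network is analyzed unweighted (characters linked when they share a
  scene); the packaged fixture keeps the co-appearance counts for the
  weighted-input machinery.

## Limitations

Directed and bipartite variants are out of scope, as are degree sequences
other than the observed one, KL-divergence NMF, hierarchical map
equations, and per-community local type decisions (the type search is
global). Model selection is by description length, not by statistical
testing. The map-equation overlap split is an instantiation calibrated on
published values of the classic networks; a different flow-splitting
convention would shift absolute MDL values (comparisons between schemes
are far less sensitive, since all schemes are scored by the same rule).
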