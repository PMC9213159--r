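---
title: "Graph partition sampling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph partition sampling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsample)
```

`gpsample` targets sparse interaction networks whose degree distribution is
long-tailed — protein–protein interaction graphs are the motivating case —
and bundles the three stages such networks need for representation
learning: sampling (biased walks, fixed-fanout neighborhoods), partitioning
(degree-ordered graph blocks, replica-cost hypergraph parts), and training
(negative-sampling SGD on four unsupervised objectives). This vignette
records the models, their assumptions, and the design decisions taken where
more than one reasonable construction existed.

## Graphs, hypergraphs and generators

Graphs are undirected, simple and positively weighted. Node identifiers are
mapped to dense 1-based integers on read and the original labels restored
on write; all invariants (symmetry, no self-loops, no duplicates, positive
weights) are enforced at construction. The combinatorial Laplacian
$L = D - A$ and its symmetric normalization $\tilde L = I - D^{-1/2} A
D^{-1/2}$ are exposed for spectral diagnostics; no spectral clustering
pipeline is built on top of them.

The power-law generator is preferential attachment: a seed clique (a
triangle for $m \le 2$), then each arriving node attaches to $m$ distinct
existing nodes chosen proportionally to current degree. With $m = 2$ the
edge count is exactly $2(n-3) + 3$. Preferential attachment was chosen
because it is the minimal, seeded, connected mechanism producing the
long-tail structure the library is about; its asymptotic density exponent
is $-3$.

`degree_distribution_stats()` fits the tail slope on a *logarithmically
binned* histogram (geometric bins of factor 2, count density per bin
against the geometric bin center). A naive least-squares fit of raw
log-count on log-degree is systematically flattened by the many degrees
observed exactly once in the tail — on $n = 2000$, $m = 2$ generator output
it reports slopes near $-1.9$ where the binned estimator reports $\approx
-2.8$, consistent with the $-3$ theory value. Log-binning is the standard
remedy and is therefore the shipped estimator. The tail share is the
fraction of edges with at least one endpoint among the top 1% of nodes by
degree (at least one node), so a star's hub scores 1.

The stochastic block model generator connects within-block pairs with
$p_{\text{in}}$ and cross-block pairs with $p_{\text{out}}$, returning the
planted labels. It is the controllable substrate for evaluating embeddings:
recovery of its labels by k-means on trained vectors, scored with the
adjusted Rand index, is the end-to-end quality check.

What the generators do *not* emulate: degree correlations, clustering
coefficients and motif structure of real PPI networks, edge weights from
interaction confidence scores, or annotation-driven communities. Passing
tests on these substrates therefore demonstrates correctness of the
machinery and qualitative behavior (hub concentration, community
separability), not biological performance.

Hypergraphs carry per-vertex weights $c(v)$ and per-net costs $c(n)$. The
random generator draws each net size uniformly from the requested range;
when total slot capacity covers the vertex set, vertices are dealt into
slots first so that coverage is achieved *within* the drawn sizes, and only
when capacity falls short are missing vertices appended (growing nets).
This keeps the exact-size contract and the everyone-covered contract
compatible whenever they can be.

## Biased walks and fixed-fanout sampling

The second-order walk uses the standard two-parameter bias: from $v$ with
predecessor $t$, neighbor $x$ gets unnormalized mass $\alpha_{pq}(t,x)\,
w_{vx}$ with $\alpha = 1/p,\ 1,\ 1/q$ for $t$–$x$ distance $0, 1, 2$.
Design choices where the scheme is silent:

- The first step of a walk has no predecessor and is uniform over
  neighbors.
- A walk reaching a node with no neighbors (possible only when the start
  node is isolated, since the graph is undirected) truncates with a
  warning rather than erroring; user-supplied edge lists can contain
  isolated labels.
- Context extraction from a walk emits ordered pairs in both directions
  within the window, matching the symmetric softmax objective. The default
  window is 5, the common skip-gram choice; it is configurable.
- Sampling is by direct normalized probability at each step; with
  $p = q = 1$ on unweighted graphs the code short-circuits to uniform
  neighbor choice. The contract is distributional, so alias tables could be
  substituted without observable change.

Fixed-fanout sampling returns exactly $K$ neighbors for every node:
truncation (uniform without replacement) above degree $K$, fill (all
neighbors at least once, remaining slots uniform with replacement) below.
The partition-aware variant restricts the candidate pool to same-block
neighbors, falling back to all neighbors when none exists; it is exposed as
an option of the GraphSage trainer and no speedup claims are attached to
it.

One statistical note recorded for reviewers of the stationarity check: the
unbiased ($p=q=1$) walk's visit frequencies converge to
$\deg(v)/2|E|$, and the test suite verifies a 2% maximum relative error at
$10^6$ steps. That tolerance is only identifiable when every node's
stationary mass is well above the Monte-Carlo noise floor, so the fixture
is a 50-node near-regular circulant (offsets 1, 2, 3, 5, 8, 13, 21:
connected, non-bipartite, expander-like). On a hub-heavy graph the
low-degree nodes' masses (~0.5%) leave per-node noise of the same order as
the tolerance, and the check would be uninformative for any seed.

## Degree-ordered partitioning

Nodes sorted by degree descending (ties by id ascending, for determinism)
are packed contiguously into blocks of capacity $\lceil n/k \rceil$, so
block 1 collects the hubs. The result satisfies the balance constraint
$W(N_i) \le (1+\varepsilon) W_{\text{avg}}$ whenever $\lceil n/k \rceil \le
(1+\varepsilon) n/k$; otherwise the partitioner refuses rather than
silently violating the constraint. The quality metrics are
$\theta = (W_{\max} - W_{\text{avg}})/W_{\text{avg}}$, the normalized size
spread $\mathrm{NSTDEV} = \sqrt{\sum_i (P_i/(P/k) - 1)^2 / k}$ (chosen as a
dimensionless, scale-invariant root-mean-square deviation of the normalized
block size from 1, zero exactly at perfect balance), normalized sizes
$P_i/P$, and the $k \times k$ block-pair edge-count matrix whose diagonal
counts intra-block edges once. No exact minimizer of the partition
objective is attempted — balanced graph partitioning is NP-hard — the
greedy rule plus metrics is the deliverable.

## Hypergraph partitioning by replica cost

Assigning whole nets to $k$ parts induces per-vertex replica counts
$\lambda(v)$ (distinct parts holding a net that contains $v$) and the
replicated set $V_R = \{v : \lambda(v) \ge 2\}$. Two costs are computed:
the vertex-cut form $\sum_{v \in V_R} c(v)$ and the replica
(connectivity-minus-one) form $\sum_{v \in V_R} (\lambda(v)-1) c(v)$. The
replica form is the optimization objective because it counts the copies
that must actually be kept consistent; the cut form is reported as a
metric. Both vanish together exactly when nothing is replicated.

The local search is this package's construction around the randomized
selection weights: initialization assigns nets round-robin in descending
size order; each iteration picks a net with size-proportional probability
(the delete weights $d(n_i)/\sum d$, with $d(n_i)$ taken to be the net
size — the natural degree of a net), proposes a uniform other part, and
accepts only strict replica-cost decreases that keep the balance constraint
(best-effort when no balanced state is reachable, with a warning). The
accepted-cost trace is therefore strictly decreasing. Restarts rerun the
search from uniform random assignments (restart 0 is the deterministic
round-robin start) and the best balanced result wins. On small instances
(up to ~6 nets) exhaustive enumeration in the test suite confirms the
search attains the optimal replica cost with 30 restarts; no optimality
guarantee holds at scale, which is inherent to local search on an NP-hard
objective.

Minimum covering-network selection (fewest nets whose union is all
vertices) ships in two forms: the classical greedy rule (largest uncovered
gain, ties to the lower net id) with its $1+\ln|V|$ guarantee, and a
branch-and-bound exact option intended for instances up to ~15 nets. It is
an independent operation; it does not feed the partition loop.

Default imbalance tolerance is $\varepsilon = 0.05$ for both partitioners —
tight enough to force near-equal parts, loose enough to absorb rounding on
small $k$.

## Embedding objectives and trainer

Every node has a source vector $f(u)$ and a context vector $u'$, both
initialized uniformly in $[-0.5/d,\ 0.5/d]$ per coordinate under the run
seed. The exact objectives are implemented for verification at test scale,
with analytic gradients (checked against central finite differences):

- node2vec: full-softmax $\Pr(n_i \mid f(u)) = \exp(f(n_i) \cdot f(u)) /
  \sum_v \exp(f(v)\cdot f(u))$ with source vectors on both sides; the
  objective sums $f(n_i)\cdot f(u) - \log Z_u$ per context pair, with
  $Z_u$ evaluated per pair. The gradient includes the dependence of $Z_u$
  on $f(u)$ itself.
- LINE first order: $p_1(v_i,v_j) = \sigma(u_i \cdot u_j)$, objective
  $-\sum_{(i,j)\in E} \omega_{ij} \log p_1$. Written as a negative
  log-likelihood to be minimized; the sign makes it non-negative and
  consistent with its relative-entropy reading.
- LINE second order: $p_2(v_j \mid v_i) = \exp(u'_j \cdot u_i)/\sum_k
  \exp(u'_k \cdot u_i)$, objective summed over both directions of each
  undirected edge, same sign convention. The per-node prestige weight that
  a fully general second-order objective would carry is set to 1 for every
  node — there is no principled per-node value available, and 1 reduces the
  objective to the edge-weighted form.
- GraphSage: $\mathcal{L} = -\log\sigma(z_u^T z_v) - N\,
  \mathbb{E}_{v_n \sim P_n}\log\sigma(-z_u^T z_{v_n})$, the expectation
  estimated by the mean over the $N$ supplied negatives; representations
  $z$ come from mean aggregation of sampled neighbor source vectors
  (elementwise mean, affine map, $\tanh$, L2 normalization; the zero vector
  maps to zero).

Full softmaxes guard overflow by max-subtraction; $\log\sigma(x)$ switches
to its linear asymptote below $x = -30$.

The trainer uses skip-gram negative sampling throughout: positives are walk
context pairs (node2vec, sage) or edges (line1; both directions for line2),
negatives are drawn from $P_n(v) \propto \deg(v)^{0.75}$ — the conventional
noise exponent, configurable. The reported trajectory is the per-epoch mean
of the per-sample surrogate loss, so it decreases for every objective.
Defaults: learning rate 0.05, 5 negatives, dimension 16, fanout 10. For
GraphSage, gradients flow through the aggregator (weights, bias) and into
the sampled neighbor vectors; backpropagation through the L2 normalization
uses the projection $(I - zz^T)/\lVert h\rVert$. Training is
bit-reproducible under the configuration seed, which drives initialization,
walk generation, shuffling and negative draws through derived substreams.

The node2vec objective's $\log Z_u$ is charged once per context pair (not
once per node); the exact-objective oracle tests pin that convention.

## Problem sizes used in the checks

The shipped verification runs use: exhaustive transition-law comparison on
every labeled graph with up to 5 nodes plus seeded 6–8 node graphs; $10^6$
walk steps for stationarity; 20 seeded 2000-node generator replicates for
tail structure and walk-range contrasts; 50 random hypergraph instances
with up to 6 nets against exhaustive enumeration; and 5 seeded 200-node
two-block graphs (within-block edge probability 0.1, cross-block 0.01,
dimension 16, 30 epochs) for end-to-end community recovery. These sizes
keep the exact oracles (full softmax sums, $k^m$ enumerations) tractable
while leaving the estimators' noise well inside the asserted tolerances.

## Known limitations

- Directed graphs, multigraphs and node attribute matrices are out of
  scope; weights enter only the walk bias and the LINE objectives.
- The hypergraph search is a single-move local search; no multilevel
  coarsening or gain tables, so large instances should expect slower
  progress per iteration than dedicated partitioners.
- Training is plain R; it is sized for method validation and moderate
  graphs (hundreds to a few thousand nodes), not for production-scale
  embedding runs.
- The partition-aware sampling flag changes which neighbors the GraphSage
  aggregator sees; no claim about training speed or quality is made or
  tested beyond end-to-end execution.
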