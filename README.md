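# gpsample

Sampling, partitioning and unsupervised embedding for large sparse
interaction networks with power-law degree structure — the regime typical of
protein–protein interaction (PPI) graphs and social comment networks, where
a handful of hub nodes carry most of the edges.

`gpsample` provides, in one coherent toolkit:

- **Biased second-order random walks** (node2vec style). From current node
  *v* with predecessor *t*, neighbor *x* is drawn with probability
  proportional to α<sub>pq</sub>(t, x)·w(v, x), where α = 1/p if *x* = *t*,
  1 if *x* is a common neighbor of *t* and *v*, and 1/q otherwise. Small *q*
  drives the walk outward (depth-first-like), large *q* keeps it local
  (breadth-first-like).
- **Fixed-fanout neighbor sampling with truncation and fill**: hubs are
  truncated to *K* distinct uniform neighbors; low-degree nodes reuse their
  neighbors with replacement until *K* slots are filled, so every node
  yields the same sample shape.
- **Degree-ordered graph partitioning**: nodes sorted by degree descending
  are packed into blocks of capacity ⌈n/k⌉, concentrating the hubs — and
  with them most edges — in the first block, plus the balance diagnostics
  θ = (W<sub>max</sub> − W<sub>avg</sub>)/W<sub>avg</sub>, the normalized
  size spread NSTDEV = √(Σ<sub>i</sub>(P<sub>i</sub>/(P/k) − 1)²/k), and
  block-pair edge-count matrices.
- **Hypergraph partitioning** by randomized local search: whole networks
  (hyperedges) are assigned to parts; a vertex held by nets in λ(v)
  distinct parts is replicated λ(v) times, and the search minimizes the
  replica (connectivity-minus-one) cost Σ<sub>v∈V_R</sub>(λ(v) − 1)c(v)
  subject to the balance constraint W(N<sub>i</sub>) ≤ (1 + ε)W<sub>avg</sub>,
  with size-proportional random move selection to escape local optima.
  Vertex-cut cost, greedy/exact minimum covering-network selection and the
  cost-proportional add / size-proportional delete selection weights are
  included.
- **Unsupervised embedding objectives** trained by SGD with negative
  sampling: the node2vec full-softmax skip-gram objective, LINE first-order
  (σ(u⃗ᵢ·u⃗ⱼ) over edges) and second-order (context-vector softmax)
  proximities, and the GraphSage graph-based loss
  −log σ(z_u·z_v) − Σ log σ(−z_u·z_vn) with mean neighbor aggregation over
  truncation/fill samples (optionally restricted to partition blocks).
- **Synthetic generators** — seeded preferential attachment (long-tail
  degree structure) and stochastic block models (planted communities) — so
  every component can be exercised end to end without external data.

Graphs are plain whitespace-separated edge lists (`u v [w]`, `#` comments);
hypergraphs use an hMETIS-like dialect (header `num_nets num_vertices`, one
line of 1-based vertex ids per net).

## Worked example

```r
library(gpsample)

g <- generate_power_law_graph(n = 500, m = 2, seed = 42)
degree_distribution_stats(g)
#> degree stats: 23 distinct degrees, tail slope -2.711, tail share 0.1605

part <- degree_partition(g, k = 4, epsilon = 0.1)
edge_block_matrix(g, part)
#>      [,1] [,2] [,3] [,4]
#> [1,]  243  220  212  180
#> [2,]  220   34   38   70
#> [3,]  212   38    0    0
#> [4,]  180   70    0    0
balance_theta(part)
#> [1] 0
```

The tail slope ≈ −2.7 and the 16% of edges touching the top-1% nodes are
the long-tail signature the partitioner exploits: the first (hub) block
holds the largest intra-block edge count (243 of 997 edges) while the
blocks stay perfectly size-balanced (θ = 0).

```r
sb  <- generate_sbm(c(100, 100), p_in = 0.1, p_out = 0.01, seed = 1)
fit <- train_embeddings(sb$graph,
                        train_config(loss = "line1", dim = 16,
                                     epochs = 30, seed = 1))
round(fit$loss_trajectory[c(1, 30)], 3)
#> [1] 4.159 4.024
evaluate_community_recovery(fit$model, sb$labels, seed = 1)
#> [1] 0.9799995
```

Thirty epochs of first-order training reduce the negative-sampling loss and
k-means on the embeddings recovers the two planted blocks almost perfectly
(adjusted Rand index 0.98).

## Command line

A thin launcher ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gpsample.R", package = "gpsample"))')
Rscript "$CLI" generate-graph --n 2000 --m 2 --seed 1 --out ppi_like.tsv
Rscript "$CLI" partition --graph ppi_like.tsv --k 4 --out blocks.tsv
Rscript "$CLI" train --graph ppi_like.tsv --loss line1 --dim 16 \
    --epochs 20 --seed 1 --out emb.tsv
```

Subcommands: `generate-graph`, `generate-hypergraph`, `walk`, `partition`,
`hpartition`, `train`, `metrics`. Flags can also come from a YAML file via
`--config` (explicit flags win), and every run writes a `.meta.json`
parameter/seed record next to its output.

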