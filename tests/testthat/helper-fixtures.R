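# Shared fixtures and independent oracles. Oracles here are deliberately
# naive re-derivations (double loops, enumeration) kept separate from the
# package's code paths.

make_triangle <- function() graph_from_edges(c(1, 1, 2), c(2, 3, 3))

make_star <- function(leaves) {
  graph_from_edges(rep(0, leaves), seq_len(leaves))
}

make_ring <- function(n) {
  graph_from_edges(seq_len(n), c(seq_len(n - 1) + 1, 1))
}

# near-regular expander-like fixture: 50-node circulant, non-bipartite
make_circulant50 <- function(offsets = c(1, 2, 3, 5, 8, 13, 21)) {
  u <- rep(1:50, each = length(offsets))
  v <- ((u - 1 + offsets) %% 50) + 1
  graph_from_edges(u, v)
}

is_connected <- function(g) all(is.finite(bfs_distances(g, 1)))

# every labeled graph on n nodes (2^C(n,2) edge subsets), as gps_graph
# objects with all n nodes present; optionally only those with >= 1 edge
all_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  out <- list()
  for (mask in 1:(2^np - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) != 0)
    out[[length(out) + 1]] <- graph_from_edges(
      pairs[1, on], pairs[2, on], isolated_labels = seq_len(n))
  }
  out
}

# random connected simple graph on n nodes: spanning tree plus extra edges
random_connected_graph <- function(n, extra = n, seed = 1) {
  withr::with_seed(seed, {
    u <- 2:n
    v <- vapply(u, function(i) sample.int(i - 1, 1), integer(1))
    pairs <- utils::combn(n, 2)
    key <- paste(pmin(u, v), pmax(u, v))
    avail <- which(!(paste(pairs[1, ], pairs[2, ]) %in% key))
    add <- sample(avail, min(extra, length(avail)))
    graph_from_edges(c(u, pairs[1, add]), c(v, pairs[2, add]))
  })
}

# direct transcription of the biased-walk transition rule: for each neighbor
# x of v, unnormalized mass (1/p if x == t, 1 if x ~ t, 1/q otherwise)
# times the edge weight, normalized
brute_step_distribution <- function(g, t, v, p, q) {
  nb <- g$adj[[v]]
  w <- g$adjw[[v]]
  alpha <- numeric(length(nb))
  for (i in seq_along(nb)) {
    x <- nb[i]
    alpha[i] <- if (x == t) 1 / p
      else if (any(g$adj[[t]] == x)) 1
      else 1 / q
  }
  pr <- alpha * w
  stats::setNames(pr / sum(pr), nb)
}

# naive two-loop full softmax Pr(ni | f(u)) without max-subtraction tricks
brute_softmax_prob <- function(S, ni, u) {
  num <- exp(sum(S[ni, ] * S[u, ]))
  den <- 0
  for (v in seq_len(nrow(S))) den <- den + exp(sum(S[v, ] * S[u, ]))
  num / den
}

brute_node2vec_objective <- function(S, pairs) {
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; ni <- pairs[r, 2]
    Z <- 0
    for (v in seq_len(nrow(S))) Z <- Z + exp(sum(S[v, ] * S[u, ]))
    total <- total + sum(S[ni, ] * S[u, ]) - log(Z)
  }
  total
}

brute_line2_prob <- function(S, C, j, i) {
  den <- 0
  for (k in seq_len(nrow(C))) den <- den + exp(sum(C[k, ] * S[i, ]))
  exp(sum(C[j, ] * S[i, ])) / den
}

# exhaustive minimum replica-variant cost over all k^m net assignments,
# restricted to assignments meeting the balance constraint (all of them if
# none does)
brute_hypergraph_optimum <- function(h, k, epsilon) {
  m <- length(h$nets)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  costs <- numeric(nrow(grid))
  feas <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    a <- hyper_assignment(h, grid[r, ], k, epsilon)
    costs[r] <- communication_cost(h, a, "replica")
    w_avg <- sum(a$part_weights) / k
    feas[r] <- all(a$part_weights <= (1 + epsilon) * w_avg)
  }
  if (any(feas)) min(costs[feas]) else min(costs)
}

# exhaustive minimum set cover by subset enumeration (instances <= ~12 nets)
brute_min_cover_size <- function(h) {
  m <- length(h$nets)
  for (size in 1:m) {
    combos <- utils::combn(m, size)
    for (c in seq_len(ncol(combos))) {
      cover <- unique(unlist(h$nets[combos[, c]]))
      if (length(cover) == h$n_vertices) return(size)
    }
  }
  m
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))
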