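# Degree-ordered graph partitioning and partition-quality metrics.
#
# The partitioner exploits the power-law structure: nodes sorted by degree
# descending are packed greedily into blocks of capacity ceil(n / k), so the
# hubs end up together in block 1 and most edges concentrate inside it.

#' Partition object
#'
#' @param assignment integer block id per node, values in `1:k`.
#' @param k number of blocks.
#' @param node_weights positive node weights, recycled; default 1.
#' @param epsilon imbalance tolerance, >= 0.
#' @return a list of class `gps_partition` with the assignment, per-block
#'   weights `W(N_i)` and sizes.
#' @export
partition <- function(assignment, k = max(assignment), node_weights = 1,
                      epsilon = 0.05) {
  assignment <- as.integer(assignment)
  if (any(assignment < 1 | assignment > k)) stop("block ids must lie in 1..k")
  w <- rep_len(as.numeric(node_weights), length(assignment))
  if (any(w <= 0)) stop("node weights must be > 0")
  bw <- vapply(seq_len(k), function(b) sum(w[assignment == b]), numeric(1))
  bs <- tabulate(assignment, nbins = k)
  structure(list(k = as.integer(k), assignment = assignment,
                 node_weights = w, block_weights = bw, block_sizes = bs,
                 epsilon = epsilon),
            class = "gps_partition")
}

#' @export
print.gps_partition <- function(x, ...) {
  cat(sprintf("gps_partition: %d nodes in %d blocks (sizes %s), epsilon %.3g\n",
              length(x$assignment), x$k, paste(x$block_sizes, collapse = "/"),
              x$epsilon))
  invisible(x)
}

#' Degree-ordered graph partitioning
#'
#' Sorts nodes by degree descending (ties broken by dense id ascending) and
#' fills blocks contiguously: block 1 takes the `ceiling(n / k)` highest-
#' degree nodes, then block 2, and so on. The result satisfies the balance
#' constraint `W(N_i) <= (1 + epsilon) * W_avg` whenever
#' `ceiling(n / k) <= (1 + epsilon) * n / k`; otherwise a balance error is
#' raised.
#'
#' @param g a `gps_graph` with `n >= k` nodes.
#' @param k number of blocks, >= 1.
#' @param epsilon imbalance tolerance, >= 0.
#' @return a `gps_partition` (unit node weights).
#' @export
degree_partition <- function(g, k, epsilon = 0.05) {
  if (k < 1) stop("k must be >= 1")
  if (g$n < k) stop("k exceeds the number of nodes")
  cap <- ceiling(g$n / k)
  if (cap > (1 + epsilon) * g$n / k) {
    stop(sprintf("infeasible balance: block capacity %d exceeds (1+eps)*n/k = %.3f",
                 cap, (1 + epsilon) * g$n / k))
  }
  d <- degree(g)
  ord <- order(-d, seq_len(g$n))
  asg <- integer(g$n)
  asg[ord] <- rep(seq_len(k), each = cap, length.out = g$n)
  partition(asg, k, epsilon = epsilon)
}

#' Balance constraint check
#'
#' `TRUE` iff every block weight satisfies
#' `W(N_i) <= (1 + epsilon) * W_avg` with `W_avg = sum(W) / k`.
#'
#' @param part a `gps_partition`.
#' @param epsilon tolerance; defaults to the partition's own.
#' @return logical.
#' @export
check_balance <- function(part, epsilon = part$epsilon) {
  w_avg <- sum(part$block_weights) / part$k
  all(part$block_weights <= (1 + epsilon) * w_avg)
}

#' Balance metric theta
#'
#' `(W_max - W_avg) / W_avg`: zero exactly at perfect weight balance,
#' invariant under uniform scaling of all weights.
#'
#' @param part a `gps_partition` with positive total weight.
#' @return non-negative scalar.
#' @export
balance_theta <- function(part) {
  if (length(part$assignment) == 0) stop("empty partition")
  w_avg <- sum(part$block_weights) / part$k
  if (w_avg <= 0) stop("average block weight must be > 0")
  (max(part$block_weights) - w_avg) / w_avg
}

#' Normalized standard deviation of block sizes
#'
#' Root-mean-square deviation of the normalized block size `P_i / (P / k)`
#' from 1: `sqrt(sum_i (P_i / (P/k) - 1)^2 / k)`. Dimensionless, zero at
#' perfect balance, invariant under uniform scaling of sizes.
#'
#' @param part a `gps_partition` with at least one node.
#' @return non-negative scalar.
#' @export
partition_size_stdev <- function(part) {
  P <- sum(part$block_sizes)
  if (P == 0) stop("empty partition")
  r <- part$block_sizes / (P / part$k)
  sqrt(sum((r - 1)^2) / part$k)
}

#' Normalized block sizes
#'
#' Per-block size divided by the total size; entries sum to 1.
#'
#' @param part a `gps_partition`.
#' @return numeric vector of length `k`.
#' @export
normalized_sizes <- function(part) {
  part$block_sizes / sum(part$block_sizes)
}

#' Block-pair edge counts
#'
#' Symmetric `k x k` matrix whose `(i, j)` entry counts edges with one
#' endpoint in block i and the other in block j; the diagonal counts
#' intra-block edges once, so the diagonal plus the upper triangle sums to
#' `|E|`.
#'
#' @param g a `gps_graph`.
#' @param part a `gps_partition` of its nodes.
#' @return integer matrix.
#' @export
edge_block_matrix <- function(g, part) {
  k <- part$k
  M <- matrix(0L, k, k)
  if (n_edges(g) > 0) {
    bi <- part$assignment[g$edges[, 1]]
    bj <- part$assignment[g$edges[, 2]]
    a <- pmin(bi, bj); b <- pmax(bi, bj)
    tab <- table(factor(a, levels = 1:k), factor(b, levels = 1:k))
    M <- matrix(as.integer(tab), k, k)
    M <- M + t(M) - diag(diag(M), k)
  }
  M
}

#' Partition-aware neighbor sampling
#'
#' As [sample_neighbors()], but the candidate pool is restricted to the
#' neighbors of `v` that share its block; when no neighbor is in the same
#' block the pool falls back to all neighbors.
#'
#' @param g a `gps_graph`.
#' @param part a `gps_partition`.
#' @param v node with degree >= 1.
#' @param K fanout, >= 1.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return integer vector of `K` dense ids.
#' @export
partition_aware_neighbor_sample <- function(g, part, v, K, seed = NULL) {
  vi <- node_index(g, v)
  nb <- g$adj[[vi]]
  if (length(nb) == 0) stop("cannot sample neighbors of an isolated node")
  pool <- nb[part$assignment[nb] == part$assignment[vi]]
  if (length(pool) == 0) pool <- nb
  sample_neighbors(g, vi, K, seed = seed, pool = pool)
}
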