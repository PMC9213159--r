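# Hypergraph partitioning by replication cost.
#
# Assigning whole nets to parts replicates shared vertices: a vertex v held
# by nets in lambda(v) distinct parts has lambda(v) copies, and every copy
# beyond the first must be kept consistent across parts. Two costs follow:
# the vertex-cut form sum_{v in V_R} c(v) over the replicated set
# V_R = {v : lambda(v) >= 2}, and the replica (connectivity-minus-one) form
# sum_{v in V_R} (lambda(v) - 1) c(v), which counts the copies directly and
# is the optimization objective here.

#' Hypergraph part assignment
#'
#' @param h a `gps_hypergraph`.
#' @param part_of integer part id per net, values in `1:k`.
#' @param k number of parts.
#' @param epsilon imbalance tolerance.
#' @return a list of class `gps_hyperassignment` holding the assignment, the
#'   replica counts `lambda(v)`, the replicated set and per-part weights
#'   `W(N_i)` (sum of `c(v)` over vertices with a copy in part i).
#' @export
hyper_assignment <- function(h, part_of, k = max(part_of), epsilon = 0.05) {
  part_of <- as.integer(part_of)
  if (length(part_of) != length(h$nets)) stop("one part id per net required")
  if (any(part_of < 1 | part_of > k)) stop("part ids must lie in 1..k")
  M <- incidence_matrix(h)
  cover <- vapply(seq_len(k), function(p) {
    sel <- part_of == p
    if (!any(sel)) return(rep(FALSE, h$n_vertices))
    rowSums(M[, sel, drop = FALSE]) > 0
  }, logical(h$n_vertices))
  cover <- matrix(cover, nrow = h$n_vertices)
  lambda <- rowSums(cover)
  part_weights <- colSums(cover * h$vertex_weights)
  structure(list(h = h, k = as.integer(k), part_of = part_of,
                 lambda = as.integer(lambda),
                 replicated = lambda >= 2,
                 part_weights = part_weights, epsilon = epsilon),
            class = "gps_hyperassignment")
}

#' @export
print.gps_hyperassignment <- function(x, ...) {
  cat(sprintf("gps_hyperassignment: %d nets in %d parts, %d replicated vertices\n",
              length(x$part_of), x$k, sum(x$replicated)))
  invisible(x)
}

#' Vertex replica counts
#'
#' `lambda(v)`: the number of distinct parts containing at least one net that
#' includes v. Always between 1 (for covered vertices) and
#' `min(k, overdegree(v))`.
#'
#' @param h a `gps_hypergraph`.
#' @param asg a `gps_hyperassignment` over `h`.
#' @return integer vector over vertices.
#' @export
replica_counts <- function(h, asg) {
  asg$lambda
}

#' Communication cost of a hypergraph partition
#'
#' Variant `"cut"` sums `c(v)` over the replicated set; variant `"replica"`
#' sums `(lambda(v) - 1) * c(v)` (connectivity minus one). Both are zero
#' exactly when no vertex is replicated.
#'
#' @param h a `gps_hypergraph`.
#' @param asg a `gps_hyperassignment`.
#' @param variant `"cut"` or `"replica"`.
#' @return non-negative scalar.
#' @export
communication_cost <- function(h, asg, variant = c("replica", "cut")) {
  variant <- match.arg(variant)
  r <- asg$replicated
  if (variant == "cut") sum(h$vertex_weights[r])
  else sum((asg$lambda[r] - 1) * h$vertex_weights[r])
}

#' Number of cut (replicated) vertices
#'
#' `|V_R|`: vertices with two or more copies.
#'
#' @param asg a `gps_hyperassignment`.
#' @return non-negative integer.
#' @export
vertex_cut_count <- function(asg) {
  sum(asg$replicated)
}

#' Balance metric theta for a hypergraph partition
#'
#' `(W_max - W_avg) / W_avg` over per-part replica weights.
#'
#' @param asg a `gps_hyperassignment`.
#' @return non-negative scalar.
#' @export
hyper_balance_theta <- function(asg) {
  w_avg <- sum(asg$part_weights) / asg$k
  if (w_avg <= 0) stop("average part weight must be > 0")
  (max(asg$part_weights) - w_avg) / w_avg
}

hyper_check_balance <- function(asg, epsilon = asg$epsilon) {
  w_avg <- sum(asg$part_weights) / asg$k
  all(asg$part_weights <= (1 + epsilon) * w_avg)
}

#' Minimal covering network selection
#'
#' Selects networks whose union is the whole vertex set. The default greedy
#' rule repeatedly picks the net covering the most still-uncovered vertices
#' (ties to the lower net id). With `exact = TRUE` (intended for instances
#' with at most ~15 nets) a branch-and-bound search returns a minimum-size
#' cover.
#'
#' @param h a `gps_hypergraph` whose nets jointly cover all vertices.
#' @param exact return a provably minimum cover.
#' @return integer vector of selected net ids (ascending).
#' @export
min_cover_networks <- function(h, exact = FALSE) {
  m <- length(h$nets)
  if (length(setdiff(seq_len(h$n_vertices), unlist(h$nets))) > 0) {
    stop("infeasible: some vertex belongs to no net")
  }
  if (!exact) {
    uncovered <- rep(TRUE, h$n_vertices)
    chosen <- integer(0)
    while (any(uncovered)) {
      gain <- vapply(h$nets, function(nn) sum(uncovered[nn]), integer(1))
      gain[chosen] <- -1L
      j <- which.max(gain)  # which.max takes the first (lowest id) on ties
      chosen <- c(chosen, j)
      uncovered[h$nets[[j]]] <- FALSE
    }
    return(sort(chosen))
  }
  # branch and bound: prune branches that cannot beat the incumbent
  best <- seq_len(m)
  M <- incidence_matrix(h)
  recurse <- function(chosen, uncovered) {
    if (!any(uncovered)) {
      if (length(chosen) < length(best)) best <<- chosen
      return(invisible(NULL))
    }
    if (length(chosen) + 1 >= length(best)) {
      # one more net must finish the cover or the branch is dead
      v <- which(uncovered)[1]
      for (j in setdiff(which(M[v, ]), chosen)) {
        left <- uncovered; left[h$nets[[j]]] <- FALSE
        if (!any(left) && length(chosen) + 1 < length(best)) best <<- c(chosen, j)
      }
      return(invisible(NULL))
    }
    v <- which(uncovered)[1]  # branch on nets covering the first uncovered vertex
    for (j in setdiff(which(M[v, ]), chosen)) {
      left <- uncovered; left[h$nets[[j]]] <- FALSE
      recurse(c(chosen, j), left)
    }
    invisible(NULL)
  }
  recurse(integer(0), rep(TRUE, h$n_vertices))
  sort(best)
}

#' Randomized network-addition probabilities
#'
#' Cost-proportional selection weights `w(n_i) = c(n_i) / sum c(n)`, used to
#' randomize which net is added so the search can escape local optima.
#'
#' @param costs positive net costs.
#' @return probability vector summing to 1.
#' @export
add_probabilities <- function(costs) {
  if (length(costs) == 0) stop("empty cost list")
  if (any(costs <= 0)) stop("costs must be > 0")
  costs / sum(costs)
}

#' Randomized network-deletion probabilities
#'
#' Size-proportional selection weights `w(n_i) = d(n_i) / sum d(n)` with
#' `d(n_i)` the network size, used to randomize which net is moved.
#'
#' @param degrees positive network sizes.
#' @return probability vector summing to 1.
#' @export
delete_probabilities <- function(degrees) {
  if (length(degrees) == 0) stop("empty degree list")
  if (any(degrees <= 0)) stop("degrees must be > 0")
  degrees / sum(degrees)
}

#' Hypergraph partitioning by randomized local search
#'
#' Minimizes the replica-variant communication cost subject to the balance
#' constraint `W(N_i) <= (1 + epsilon) * W_avg`. The initial assignment
#' places nets in descending size order round-robin over the parts; each
#' iteration proposes moving one net — chosen with size-proportional
#' probability ([delete_probabilities()]) — to a uniformly chosen other
#' part, and accepts the move iff the cost strictly decreases and the moved
#' assignment is balanced (when no balanced assignment is reachable the
#' balance is enforced best-effort and a warning is attached). Additional
#' `restarts` rerun the search from random initial assignments; restart 0 is
#' the deterministic round-robin start. The best assignment over all
#' restarts is returned.
#'
#' @param h a `gps_hypergraph`.
#' @param k number of parts, >= 1.
#' @param epsilon imbalance tolerance.
#' @param iters proposal count per restart.
#' @param seed integer seed.
#' @param restarts extra random restarts (0 = round-robin start only).
#' @return a `gps_hyperassignment`; attribute `"cost_trace"` holds the
#'   accepted-move cost sequence (strictly decreasing) of the winning
#'   restart, and attribute `"balanced"` says whether the balance constraint
#'   is met.
#' @export
partition_hypergraph <- function(h, k, epsilon = 0.05, iters = 200, seed = 1,
                                 restarts = 0) {
  if (k < 1) stop("k must be >= 1")
  m <- length(h$nets)
  sizes <- vapply(h$nets, length, integer(1))
  move_prob <- delete_probabilities(sizes)
  rr_init <- integer(m)
  rr_init[order(-sizes, seq_len(m))] <- rep_len(seq_len(k), m)

  search_from <- function(init) {
    cur <- hyper_assignment(h, init, k, epsilon)
    cur_cost <- communication_cost(h, cur, "replica")
    cur_bal <- hyper_check_balance(cur)
    trace <- cur_cost
    if (k > 1 && m > 1) {
      for (it in seq_len(iters)) {
        net <- sample.int(m, 1, prob = move_prob)
        tgt <- sample(setdiff(seq_len(k), cur$part_of[net]), 1)
        prop <- cur$part_of
        prop[net] <- tgt
        cand <- hyper_assignment(h, prop, k, epsilon)
        cand_cost <- communication_cost(h, cand, "replica")
        cand_bal <- hyper_check_balance(cand)
        ok_bal <- if (cur_bal) cand_bal else {
          # best-effort: never worsen imbalance while unbalanced
          cand_bal || hyper_balance_theta(cand) <= hyper_balance_theta(cur)
        }
        if (cand_cost < cur_cost && ok_bal) {
          cur <- cand; cur_cost <- cand_cost; cur_bal <- cand_bal
          trace <- c(trace, cur_cost)
        }
      }
    }
    list(asg = cur, cost = cur_cost, balanced = cur_bal, trace = trace)
  }

  withr::with_seed(as.integer(seed), {
    best <- search_from(rr_init)
    if (restarts > 0 && k > 1) {
      for (r in seq_len(restarts)) {
        res <- search_from(sample.int(k, m, replace = TRUE))
        better <- (res$balanced && !best$balanced) ||
          (res$balanced == best$balanced && res$cost < best$cost)
        if (better) best <- res
      }
    }
    if (!best$balanced) {
      warning("no balanced assignment found under epsilon; best-effort result")
    }
    out <- best$asg
    attr(out, "cost_trace") <- best$trace
    attr(out, "balanced") <- best$balanced
    out
  })
}
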