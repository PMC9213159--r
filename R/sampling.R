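# Biased second-order random walks and fixed-fanout neighbor sampling.
#
# The walk follows the node2vec scheme: from current node v with predecessor
# t, a neighbor x is drawn with probability proportional to
# alpha_pq(t, x) * w(v, x), where alpha depends on the t-x shortest distance
# d_tx in {0, 1, 2}: 1/p at distance 0 (return), 1 at distance 1, 1/q at
# distance 2. Small q pushes the walk outward (depth-first-like), large q
# keeps it local (breadth-first-like).

#' Walk configuration
#'
#' @param p return parameter, > 0: small p makes revisiting the previous node
#'   likely.
#' @param q in-out parameter, > 0: small q favors moving away from the
#'   previous node.
#' @param l walk length in steps (a walk has `l + 1` nodes).
#' @param walks_per_node walks started from every node per corpus.
#' @param window context window for pair extraction.
#' @param seed integer seed.
#' @return a list of class `gps_walk_config`.
#' @export
walk_config <- function(p = 1, q = 1, l = 80, walks_per_node = 10,
                        window = 5, seed = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0")
  if (l < 1) stop("walk length must be >= 1")
  if (window < 1) stop("window must be >= 1")
  if (walks_per_node < 1) stop("walks_per_node must be >= 1")
  structure(list(p = p, q = q, l = as.integer(l),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "gps_walk_config")
}

#' Second-order transition bias
#'
#' The unnormalized search bias of the biased walk: `1/p` when the candidate
#' is the predecessor itself (`d_tx = 0`), `1` when it is a common neighbor
#' (`d_tx = 1`), `1/q` when it moves away (`d_tx = 2`).
#'
#' @param p,q positive walk parameters.
#' @param d_tx shortest distance from the predecessor to the candidate, in
#'   \{0, 1, 2\}.
#' @return a positive scalar.
#' @export
transition_bias <- function(p, q, d_tx) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0")
  if (!d_tx %in% c(0, 1, 2)) stop("d_tx must be 0, 1 or 2")
  if (d_tx == 0) 1 / p else if (d_tx == 1) 1 else 1 / q
}

#' One-step transition distribution of the biased walk
#'
#' Probability over the neighbors of the current node `v`, given the
#' predecessor `t`: each neighbor x gets unnormalized mass
#' `alpha_pq(t, x) * w(v, x)`, normalized to sum to 1. With `t = NULL`
#' (first step of a walk, no predecessor) the distribution is uniform over
#' the neighbors of `v`.
#'
#' @param g a `gps_graph`.
#' @param t predecessor dense id, or `NULL`.
#' @param v current node dense id.
#' @param p,q walk parameters.
#' @return named numeric vector of probabilities over the neighbors of `v`
#'   (names are dense ids).
#' @export
step_distribution <- function(g, t, v, p = 1, q = 1) {
  v <- node_index(g, v)
  nb <- g$adj[[v]]
  if (length(nb) == 0) stop("node has no neighbors; walk cannot continue")
  w <- g$adjw[[v]]
  if (is.null(t)) {
    pr <- rep(1, length(nb))  # first step: no predecessor, uniform
  } else {
    t <- node_index(g, t)
    tn <- g$adj[[t]]
    alpha <- ifelse(nb == t, 1 / p, ifelse(nb %in% tn, 1, 1 / q))
    pr <- alpha * w
  }
  pr <- pr / sum(pr)
  stats::setNames(pr, nb)
}

#' Biased random walk
#'
#' Generates a single walk of `cfg$l` steps from source `u`. The first step
#' has no predecessor and is uniform over neighbors; later steps follow
#' [step_distribution()]. A dead end truncates the walk with a warning.
#'
#' @param g a `gps_graph`.
#' @param u source node (label or dense id).
#' @param cfg a [walk_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return integer vector of dense node ids, length `cfg$l + 1` unless
#'   truncated.
#' @export
random_walk <- function(g, u, cfg, seed = NULL) {
  run <- function() {
    u <- node_index(g, u)
    path <- integer(cfg$l + 1)
    path[1] <- u
    if (length(g$adj[[u]]) == 0) {
      warning("walk truncated at a dead end")
      return(path[1])
    }
    prev <- NA_integer_
    cur <- u
    uniform <- cfg$p == 1 && cfg$q == 1 &&
      all(vapply(g$adjw, function(w) all(w == 1), logical(1)))
    for (s in seq_len(cfg$l)) {
      nb <- g$adj[[cur]]
      if (length(nb) == 0) {
        warning("walk truncated at a dead end")
        return(path[seq_len(s)])
      }
      if (uniform || is.na(prev)) {
        nxt <- nb[sample.int(length(nb), 1L)]
      } else {
        pr <- step_distribution(g, prev, cur, cfg$p, cfg$q)
        nxt <- nb[sample.int(length(nb), 1L, prob = pr)]
      }
      path[s + 1] <- nxt
      prev <- cur
      cur <- nxt
    }
    path
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a walk corpus
#'
#' Starts `cfg$walks_per_node` walks from every node; the start order is
#' reshuffled for each sweep. Reproducible under `cfg$seed`.
#'
#' @param g a non-empty `gps_graph`.
#' @param cfg a [walk_config()].
#' @return list of integer walk vectors (dense ids).
#' @export
generate_walk_corpus <- function(g, cfg) {
  if (g$n == 0) stop("empty graph")
  withr::with_seed(cfg$seed, {
    out <- vector("list", g$n * cfg$walks_per_node)
    k <- 0L
    for (rep in seq_len(cfg$walks_per_node)) {
      for (u in sample.int(g$n)) {
        k <- k + 1L
        out[[k]] <- random_walk(g, u, cfg)
      }
    }
    out
  })
}

#' Skip-gram context pairs from a walk
#'
#' For every position i in the sequence, emits ordered pairs
#' `(seq[i], seq[j])` for all j with `0 < |i - j| <= window`. These are the
#' positive (center, context) pairs of the walk-based objectives.
#'
#' @param seq integer node sequence.
#' @param window positive window radius.
#' @return 2-column integer matrix (`center`, `context`); zero rows for
#'   sequences of length < 2.
#' @export
context_pairs <- function(seq, window) {
  if (window < 1) stop("window must be >= 1")
  L <- length(seq)
  if (L < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("center", "context"))))
  ctr <- integer(0); ctx <- integer(0)
  for (i in seq_len(L)) {
    j <- setdiff(max(1, i - window):min(L, i + window), i)
    ctr <- c(ctr, rep(i, length(j)))
    ctx <- c(ctx, j)
  }
  out <- cbind(center = seq[ctr], context = seq[ctx])
  out
}

#' Fixed-fanout neighbor sampling with truncation and fill
#'
#' Always returns exactly `K` neighbor ids. High-degree nodes are truncated:
#' `K` distinct neighbors drawn uniformly without replacement. Low-degree
#' nodes are filled: every neighbor appears at least once and the remaining
#' slots are drawn uniformly with replacement from the neighbor set.
#'
#' @param g a `gps_graph`.
#' @param v node (label or dense id) with degree >= 1.
#' @param K fanout, >= 1.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param pool optional integer vector restricting the candidate neighbors
#'   (used by partition-aware sampling); must be non-empty.
#' @return integer vector of `K` dense ids.
#' @export
sample_neighbors <- function(g, v, K, seed = NULL, pool = NULL) {
  run <- function() {
    v <- node_index(g, v)
    nb <- if (is.null(pool)) g$adj[[v]] else pool
    d <- length(nb)
    if (d == 0) stop("cannot sample neighbors of an isolated node")
    if (K < 1) stop("K must be >= 1")
    if (d >= K) {
      nb[sample.int(d, K)]
    } else {
      extra <- nb[sample.int(d, K - d, replace = TRUE)]
      out <- c(nb, extra)
      out[sample.int(K)]  # shuffle so guaranteed copies are not positional
    }
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
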