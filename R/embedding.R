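# Unsupervised embedding objectives and their SGD trainer.
#
# Every node carries two d-vectors: a source vector f(u) and a context
# vector u'. The node2vec softmax and the LINE first-order objective use
# source vectors on both sides; the LINE second-order softmax conditions a
# context vector on a source vector. GraphSage representations z are built
# on the fly by mean-aggregating sampled neighbor source vectors.

sigmoid <- function(x) 1 / (1 + exp(-x))

# log sigmoid with a stable tail for large negative arguments
log_sigmoid <- function(x) ifelse(x > -30, -log1p(exp(-x)), x)

#' Embedding model
#'
#' Per-node source and context vectors, initialized uniformly in
#' `[-0.5/d, 0.5/d]` per coordinate.
#'
#' @param n number of nodes.
#' @param d embedding dimension.
#' @param seed integer seed for initialization.
#' @param scale half-width of the uniform initialization times `d`
#'   (default 0.5 gives the `[-0.5/d, 0.5/d]` range).
#' @return a list of class `gps_embedding` with matrices `source` and
#'   `context` (`n x d`).
#' @export
embedding_model <- function(n, d, seed = 1, scale = 0.5) {
  withr::with_seed(as.integer(seed), {
    lim <- scale / d
    structure(list(
      n = as.integer(n), d = as.integer(d),
      source = matrix(stats::runif(n * d, -lim, lim), n, d),
      context = matrix(stats::runif(n * d, -lim, lim), n, d)
    ), class = "gps_embedding")
  })
}

#' @export
print.gps_embedding <- function(x, ...) {
  cat(sprintf("gps_embedding: %d nodes, dimension %d\n", x$n, x$d))
  invisible(x)
}

#' Full-softmax context probability (node2vec)
#'
#' `Pr(n_i | f(u)) = exp(f(n_i).f(u)) / sum_v exp(f(v).f(u))` over all nodes
#' v, source vectors on both sides. Overflow is guarded by subtracting the
#' maximum score.
#'
#' @param m a `gps_embedding`.
#' @param n_i,u node ids (1-based).
#' @return probability in (0, 1).
#' @export
softmax_context_prob <- function(m, n_i, u) {
  scores <- as.vector(m$source %*% m$source[u, ])
  scores <- scores - max(scores)
  e <- exp(scores)
  e[n_i] / sum(e)
}

#' node2vec skip-gram objective (full softmax)
#'
#' `sum over pairs of [ f(n_i).f(u) - log Z_u ]` with
#' `Z_u = sum_v exp(f(v).f(u))` evaluated per pair. This is the exact
#' maximization objective; it is tractable at test scale only.
#'
#' @param m a `gps_embedding`.
#' @param pairs 2-column matrix of (center, context) node ids, e.g. from
#'   [context_pairs()].
#' @return scalar objective (higher is better).
#' @export
node2vec_objective <- function(m, pairs) {
  if (nrow(pairs) == 0) return(0)
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; ni <- pairs[r, 2]
    scores <- as.vector(m$source %*% m$source[u, ])
    mx <- max(scores)
    logZ <- mx + log(sum(exp(scores - mx)))
    total <- total + scores[ni] - logZ
  }
  total
}

#' Gradient of the node2vec full-softmax objective
#'
#' Analytic gradient of [node2vec_objective()] with respect to the source
#' matrix, including the dependence of `Z_u` on `f(u)` itself.
#'
#' @param m a `gps_embedding`.
#' @param pairs 2-column (center, context) matrix.
#' @return `n x d` gradient matrix (ascent direction).
#' @export
node2vec_objective_gradient <- function(m, pairs) {
  S <- m$source
  G <- matrix(0, m$n, m$d)
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; ni <- pairs[r, 2]
    scores <- as.vector(S %*% S[u, ])
    p <- exp(scores - max(scores)); p <- p / sum(p)
    G[ni, ] <- G[ni, ] + S[u, ]
    G[u, ] <- G[u, ] + S[ni, ]
    # d logZ/dS[w,] = p_w f(u) + 1{w=u} sum_v p_v f(v)
    G <- G - outer(p, S[u, ])
    G[u, ] <- G[u, ] - colSums(p * S)
  }
  G
}

#' Negative-sampling surrogate objective
#'
#' Skip-gram-with-negative-sampling estimator of the softmax objective:
#' `sum over pairs [ log sig(f(n_i).f(u)) + sum_{j=1..N} log sig(-f(v_j).f(u)) ]`
#' with noise nodes drawn from `P_n(v) ~ degree(v)^exponent`.
#'
#' @param m a `gps_embedding`.
#' @param pairs 2-column (center, context) matrix.
#' @param N negatives per positive pair.
#' @param degrees node degree vector defining the noise distribution.
#' @param exponent noise-distribution exponent (default 0.75).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return scalar objective (higher is better).
#' @export
negative_sampling_objective <- function(m, pairs, N, degrees,
                                        exponent = 0.75, seed = NULL) {
  if (N < 1) stop("N must be >= 1")
  run <- function() {
    pn <- degrees^exponent
    pn <- pn / sum(pn)
    total <- 0
    for (r in seq_len(nrow(pairs))) {
      u <- pairs[r, 1]; ni <- pairs[r, 2]
      total <- total + log_sigmoid(sum(m$source[ni, ] * m$source[u, ]))
      negs <- sample.int(m$n, N, replace = TRUE, prob = pn)
      for (v in negs) {
        total <- total + log_sigmoid(-sum(m$source[v, ] * m$source[u, ]))
      }
    }
    total
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' First-order proximity probability (LINE)
#'
#' `p1(v_i, v_j) = 1 / (1 + exp(-u_i . u_j))`: the sigmoid of the source-
#' vector dot product; symmetric in its arguments.
#'
#' @param m a `gps_embedding`.
#' @param v_i,v_j node ids.
#' @return probability in (0, 1).
#' @export
line1_prob <- function(m, v_i, v_j) {
  sigmoid(sum(m$source[v_i, ] * m$source[v_j, ]))
}

#' First-order proximity objective (LINE)
#'
#' Negative weighted log-likelihood over edges,
#' `O1 = - sum_{(i,j) in E} w_ij log p1(v_i, v_j)`; non-negative, minimized
#' when connected pairs have large positive dot products.
#'
#' @param m a `gps_embedding`.
#' @param g a `gps_graph`.
#' @return scalar >= 0.
#' @export
line1_objective <- function(m, g) {
  if (n_edges(g) == 0) return(0)
  dots <- rowSums(m$source[g$edges[, 1], , drop = FALSE] *
                  m$source[g$edges[, 2], , drop = FALSE])
  -sum(g$weights * log_sigmoid(dots))
}

#' Gradient of the first-order objective
#'
#' @param m a `gps_embedding`.
#' @param g a `gps_graph`.
#' @return `n x d` gradient of [line1_objective()] with respect to the
#'   source matrix (descent is minus this).
#' @export
line1_objective_gradient <- function(m, g) {
  G <- matrix(0, m$n, m$d)
  for (r in seq_len(n_edges(g))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]; w <- g$weights[r]
    coef <- -w * (1 - sigmoid(sum(m$source[i, ] * m$source[j, ])))
    G[i, ] <- G[i, ] + coef * m$source[j, ]
    G[j, ] <- G[j, ] + coef * m$source[i, ]
  }
  G
}

#' Second-order proximity probability (LINE)
#'
#' `p2(v_j | v_i) = exp(u'_j . u_i) / sum_k exp(u'_k . u_i)`: context vector
#' of the conditioned node against the source vector of the conditioning
#' node; sums to 1 over j.
#'
#' @param m a `gps_embedding`.
#' @param v_j conditioned node.
#' @param v_i conditioning node.
#' @return probability in (0, 1).
#' @export
line2_prob <- function(m, v_j, v_i) {
  scores <- as.vector(m$context %*% m$source[v_i, ])
  scores <- scores - max(scores)
  e <- exp(scores)
  e[v_j] / sum(e)
}

#' Second-order proximity objective (LINE)
#'
#' `O2 = - sum w_ij log p2(v_j | v_i)` summed over both directions of every
#' undirected edge; non-negative.
#'
#' @param m a `gps_embedding`.
#' @param g a `gps_graph`.
#' @return scalar >= 0.
#' @export
line2_objective <- function(m, g) {
  if (n_edges(g) == 0) return(0)
  total <- 0
  for (r in seq_len(n_edges(g))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]; w <- g$weights[r]
    total <- total - w * log(line2_prob(m, j, i)) - w * log(line2_prob(m, i, j))
  }
  total
}

#' Gradient of the second-order objective
#'
#' @param m a `gps_embedding`.
#' @param g a `gps_graph`.
#' @return list with `source` and `context` gradient matrices of
#'   [line2_objective()].
#' @export
line2_objective_gradient <- function(m, g) {
  S <- m$source; C <- m$context
  GS <- matrix(0, m$n, m$d); GC <- matrix(0, m$n, m$d)
  dir_term <- function(i, j, w) {
    # -w log p2(j | i)
    scores <- as.vector(C %*% S[i, ])
    p <- exp(scores - max(scores)); p <- p / sum(p)
    GC[j, ] <<- GC[j, ] - w * S[i, ]
    GC <<- GC + w * outer(p, S[i, ])
    GS[i, ] <<- GS[i, ] - w * (C[j, ] - colSums(p * C))
  }
  for (r in seq_len(n_edges(g))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]; w <- g$weights[r]
    dir_term(i, j, w)
    dir_term(j, i, w)
  }
  list(source = GS, context = GC)
}

#' GraphSage graph-based loss
#'
#' `L(z_u) = -log sig(z_u . z_v) - N * E_{vn ~ Pn} log sig(-z_u . z_vn)`,
#' with the expectation estimated by the mean over the supplied negative
#' vectors (`N` = number of negatives). Non-negative; equals
#' `(1 + N) log 2` when all vectors are zero.
#'
#' @param z_u,z_v numeric vectors (positive pair).
#' @param z_negatives matrix with one negative vector per row (or a single
#'   vector), at least one.
#' @return scalar loss >= 0.
#' @export
sage_loss <- function(z_u, z_v, z_negatives) {
  if (is.null(dim(z_negatives))) z_negatives <- matrix(z_negatives, nrow = 1)
  N <- nrow(z_negatives)
  if (N < 1) stop("at least one negative vector required")
  # N * (sample mean over the N negatives) = plain sum
  -log_sigmoid(sum(z_u * z_v)) -
    sum(log_sigmoid(-as.vector(z_negatives %*% z_u)))
}

#' Gradient of the GraphSage loss
#'
#' @param z_u,z_v,z_negatives as in [sage_loss()].
#' @return list with `z_u`, `z_v` gradient vectors and `z_negatives`
#'   gradient matrix.
#' @export
sage_loss_gradient <- function(z_u, z_v, z_negatives) {
  if (is.null(dim(z_negatives))) z_negatives <- matrix(z_negatives, nrow = 1)
  s_pos <- sigmoid(sum(z_u * z_v))
  s_neg <- sigmoid(as.vector(z_negatives %*% z_u))
  gu <- -(1 - s_pos) * z_v + colSums(s_neg * z_negatives)
  gv <- -(1 - s_pos) * z_u
  gn <- outer(s_neg, z_u)
  list(z_u = gu, z_v = gv, z_negatives = gn)
}

#' Mean neighbor aggregation
#'
#' Elementwise mean of the neighbor vectors, affine transform, `tanh`
#' nonlinearity, then L2 normalization to unit length (a zero vector maps to
#' zero). Symmetric in the neighbor order.
#'
#' @param W `d_out x d_in` weight matrix.
#' @param b length-`d_out` bias.
#' @param neighbor_vectors matrix with one neighbor vector per row (or a
#'   single vector); at least one row.
#' @param linear skip the `tanh` (used when the aggregation should be the
#'   identity map for testing).
#' @return length-`d_out` unit (or zero) vector.
#' @export
aggregate_mean <- function(W, b, neighbor_vectors, linear = FALSE) {
  if (is.null(dim(neighbor_vectors))) {
    neighbor_vectors <- matrix(neighbor_vectors, nrow = 1)
  }
  if (nrow(neighbor_vectors) == 0) stop("at least one neighbor vector required")
  mu <- colMeans(neighbor_vectors)
  a <- as.vector(W %*% mu) + b
  h <- if (linear) a else tanh(a)
  nrm <- sqrt(sum(h^2))
  if (nrm == 0) h else h / nrm
}

# forward pass of aggregate_mean keeping intermediates for backprop
aggregate_forward <- function(W, b, X) {
  mu <- colMeans(X)
  a <- as.vector(W %*% mu) + b
  h <- tanh(a)
  nrm <- sqrt(sum(h^2))
  z <- if (nrm == 0) h else h / nrm
  list(z = z, h = h, nrm = nrm, mu = mu, X = X)
}

# backprop dL/dz through normalize -> tanh -> affine -> mean
aggregate_backward <- function(W, fw, gz) {
  if (fw$nrm == 0) return(list(W = matrix(0, nrow(W), ncol(W)),
                               b = rep(0, nrow(W)),
                               X = matrix(0, nrow(fw$X), ncol(fw$X))))
  z <- fw$h / fw$nrm
  gh <- (gz - z * sum(z * gz)) / fw$nrm
  ga <- gh * (1 - fw$h^2)
  gW <- outer(ga, fw$mu)
  gmu <- as.vector(t(W) %*% ga)
  gX <- matrix(gmu / nrow(fw$X), nrow(fw$X), length(gmu), byrow = TRUE)
  list(W = gW, b = ga, X = gX)
}
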