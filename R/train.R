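# Stochastic-gradient training of the embedding objectives.
#
# All four losses are trained with skip-gram-style negative sampling:
# positives are walk context pairs (node2vec, sage) or edges (line1, line2),
# negatives are drawn from P_n(v) ~ degree(v)^exponent. The reported
# per-epoch loss is the epoch mean of the per-sample negative-sampling loss
# -[log sig(pos) + sum log sig(-neg)], so lower is better for every loss.

#' Training configuration
#'
#' @param loss one of `"node2vec"`, `"line1"`, `"line2"`, `"sage"`.
#' @param dim embedding dimension.
#' @param lr learning rate, > 0.
#' @param epochs number of passes over the positives, >= 1.
#' @param negatives noise samples per positive, >= 1.
#' @param noise_exponent exponent of the degree-based noise distribution.
#' @param fanout neighbor-sample size K for the sage aggregator.
#' @param partition_aware restrict sage neighbor sampling to the node's
#'   block of a degree partition.
#' @param k blocks for the partition when `partition_aware`.
#' @param epsilon balance tolerance for that partition.
#' @param p,q,walk_length,walks_per_node,window walk parameters for the
#'   walk-based losses.
#' @param seed integer seed controlling walks, negatives and initialization.
#' @return a list of class `gps_train_config`.
#' @export
train_config <- function(loss = c("node2vec", "line1", "line2", "sage"),
                         dim = 16, lr = 0.05, epochs = 10, negatives = 5,
                         noise_exponent = 0.75, fanout = 10,
                         partition_aware = FALSE, k = 4, epsilon = 0.05,
                         p = 1, q = 1, walk_length = 20, walks_per_node = 5,
                         window = 5, seed = 1) {
  loss <- match.arg(loss)
  if (lr <= 0) stop("learning rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (negatives < 1) stop("negatives must be >= 1")
  structure(list(loss = loss, dim = as.integer(dim), lr = lr,
                 epochs = as.integer(epochs), negatives = as.integer(negatives),
                 noise_exponent = noise_exponent, fanout = as.integer(fanout),
                 partition_aware = isTRUE(partition_aware), k = as.integer(k),
                 epsilon = epsilon, p = p, q = q,
                 walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "gps_train_config")
}

#' Train node embeddings
#'
#' Runs SGD with negative sampling on the configured objective. node2vec and
#' sage draw positives from a biased-walk corpus; line1 and line2 iterate
#' over the edge list (line2 over both directions). The sage representation
#' of a node is the mean aggregation of `fanout` sampled neighbor source
#' vectors (block-restricted when `partition_aware`), with gradients flowing
#' into the aggregator weights and the neighbor vectors. Training is
#' bit-reproducible under `cfg$seed`.
#'
#' @param g a connected `gps_graph` (a warning is emitted otherwise).
#' @param cfg a [train_config()].
#' @return list with `model` (a `gps_embedding`), `loss_trajectory`
#'   (per-epoch mean loss, lower is better) and, for sage, the aggregator
#'   `W` and `b`.
#' @export
train_embeddings <- function(g, cfg) {
  n <- g$n
  if (n < 2) stop("graph too small to train on")
  deg <- degree(g)
  if (any(deg == 0)) warning("graph has isolated nodes; they stay at initialization")
  comp <- connected_components(g)
  if (max(comp) > 1) warning("graph is not connected; training proceeds per component")
  pn <- deg^cfg$noise_exponent
  if (all(pn == 0)) pn <- rep(1, n)
  pn <- pn / sum(pn)

  m <- embedding_model(n, cfg$dim, seed = cfg$seed)
  part <- if (cfg$partition_aware) degree_partition(g, cfg$k, cfg$epsilon) else NULL

  withr::with_seed(cfg$seed + 1L, {
    positives <- switch(cfg$loss,
      line1 = g$edges,
      line2 = rbind(g$edges, g$edges[, c(2, 1), drop = FALSE]),
      {
        wcfg <- walk_config(p = cfg$p, q = cfg$q, l = cfg$walk_length,
                            walks_per_node = cfg$walks_per_node,
                            window = cfg$window, seed = cfg$seed + 2L)
        corpus <- generate_walk_corpus(g, wcfg)
        do.call(rbind, lapply(corpus, context_pairs, window = cfg$window))
      })
    if (is.null(positives) || nrow(positives) == 0) stop("no positive samples")

    W <- NULL; b <- NULL
    if (cfg$loss == "sage") {
      lim <- 1 / sqrt(cfg$dim)
      W <- matrix(stats::runif(cfg$dim^2, -lim, lim), cfg$dim, cfg$dim)
      b <- rep(0, cfg$dim)
    }

    nsamp <- nrow(positives)
    traj <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nsamp)
      negs <- matrix(sample.int(n, nsamp * cfg$negatives, replace = TRUE,
                                prob = pn),
                     nsamp, cfg$negatives)
      ep_loss <- 0
      for (s in seq_len(nsamp)) {
        u <- positives[ord[s], 1]; v <- positives[ord[s], 2]
        vn <- negs[s, ]
        if (cfg$loss == "sage") {
          res <- sgd_step_sage(g, m, W, b, u, v, vn, cfg, part)
          m <- res$m; W <- res$W; b <- res$b
          ep_loss <- ep_loss + res$loss
        } else {
          res <- sgd_step_sg(m, u, v, vn, cfg)
          m <- res$m
          ep_loss <- ep_loss + res$loss
        }
      }
      traj[ep] <- ep_loss / nsamp
      if (!is.finite(traj[ep])) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep))
      }
    }
    out <- list(model = m, loss_trajectory = traj)
    if (cfg$loss == "sage") { out$W <- W; out$b <- b }
    out
  })
}

# one negative-sampling step for node2vec / line1 (source-source) and
# line2 (source-context)
sgd_step_sg <- function(m, u, v, vn, cfg) {
  lr <- cfg$lr
  ctx <- cfg$loss == "line2"
  su <- m$source[u, ]
  tv <- if (ctx) m$context[v, ] else m$source[v, ]
  dp <- sum(su * tv)
  s <- sigmoid(dp)
  loss <- -log_sigmoid(dp)
  gu <- -(1 - s) * tv
  gtv <- -(1 - s) * su
  if (ctx) m$context[v, ] <- tv - lr * gtv else m$source[v, ] <- tv - lr * gtv
  for (w in vn) {
    tw <- if (ctx) m$context[w, ] else m$source[w, ]
    dn <- sum(su * tw)
    sn <- sigmoid(dn)
    loss <- loss - log_sigmoid(-dn)
    gu <- gu + sn * tw
    gtw <- sn * su
    if (ctx) m$context[w, ] <- tw - lr * gtw else m$source[w, ] <- tw - lr * gtw
  }
  m$source[u, ] <- su - lr * gu
  list(m = m, loss = loss)
}

# one step of the sage objective: aggregate u, v and negatives, apply the
# loss gradient, backprop into W, b and the sampled neighbor source vectors
sgd_step_sage <- function(g, m, W, b, u, v, vn, cfg, part) {
  lr <- cfg$lr
  agg_of <- function(node) {
    nb <- if (is.null(part)) sample_neighbors(g, node, cfg$fanout)
          else partition_aware_neighbor_sample(g, part, node, cfg$fanout)
    fw <- aggregate_forward(W, b, m$source[nb, , drop = FALSE])
    fw$nb <- nb
    fw
  }
  fu <- agg_of(u); fv <- agg_of(v)
  fns <- lapply(vn, agg_of)
  zneg <- do.call(rbind, lapply(fns, `[[`, "z"))
  loss <- sage_loss(fu$z, fv$z, zneg)
  gr <- sage_loss_gradient(fu$z, fv$z, zneg)
  gW <- matrix(0, nrow(W), ncol(W)); gb <- rep(0, length(b))
  apply_back <- function(fw, gz) {
    bk <- aggregate_backward(W, fw, gz)
    gW <<- gW + bk$W; gb <<- gb + bk$b
    for (i in seq_along(fw$nb)) {
      m$source[fw$nb[i], ] <<- m$source[fw$nb[i], ] - lr * bk$X[i, ]
    }
  }
  apply_back(fu, gr$z_u)
  apply_back(fv, gr$z_v)
  for (i in seq_along(fns)) apply_back(fns[[i]], gr$z_negatives[i, ])
  W <- W - lr * gW
  b <- b - lr * gb
  list(m = m, W = W, b = b, loss = loss)
}

# connected components by breadth-first search; returns component id per node
connected_components <- function(g) {
  comp <- integer(g$n)
  cid <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nb <- g$adj[[cur]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Community recovery score of an embedding
#'
#' Runs seeded k-means (k = number of distinct labels) on the source vectors
#' and scores the clustering against the labels with the adjusted Rand
#' index.
#'
#' @param m a `gps_embedding`.
#' @param labels ground-truth block id per node.
#' @param seed integer seed for k-means.
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
evaluate_community_recovery <- function(m, labels, seed = 1) {
  if (length(labels) != m$n) stop("one label per node required")
  kk <- length(unique(labels))
  if (m$n < kk) stop("fewer nodes than clusters")
  withr::with_seed(as.integer(seed), {
    cl <- stats::kmeans(m$source, centers = kk, nstart = 10)$cluster
  })
  mclust::adjustedRandIndex(cl, labels)
}
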