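#' @importFrom stats rbinom runif setNames lm coef sd
#' @importFrom utils head tail
NULL

# Internal constructor. `edges` is an m x 2 integer matrix of 1-based dense
# ids with edges[,1] < edges[,2]; `weights` positive numeric length m;
# `labels` character vector length n mapping dense id -> external label.
new_graph <- function(n, edges, weights, labels) {
  stopifnot(is.matrix(edges) || (is.null(dim(edges)) && length(edges) == 0))
  if (length(edges) == 0) edges <- matrix(integer(0), ncol = 2)
  storage.mode(edges) <- "integer"
  adj <- vector("list", n)
  adjw <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer(0)
    adjw[[i]] <- numeric(0)
  }
  if (nrow(edges) > 0) {
    # build neighbor lists sorted by neighbor id
    all_src <- c(edges[, 1], edges[, 2])
    all_dst <- c(edges[, 2], edges[, 1])
    all_w <- c(weights, weights)
    o <- order(all_src, all_dst)
    all_src <- all_src[o]; all_dst <- all_dst[o]; all_w <- all_w[o]
    split_dst <- split(all_dst, factor(all_src, levels = seq_len(n)))
    split_w <- split(all_w, factor(all_src, levels = seq_len(n)))
    for (i in seq_len(n)) {
      adj[[i]] <- as.integer(split_dst[[i]])
      adjw[[i]] <- as.numeric(split_w[[i]])
    }
  }
  structure(
    list(n = n, edges = edges, weights = as.numeric(weights),
         labels = as.character(labels), adj = adj, adjw = adjw),
    class = "gps_graph"
  )
}

#' Build a graph from an edge data frame
#'
#' Constructs an undirected, simple, weighted graph. Node identifiers may be
#' arbitrary labels; internally they are mapped to dense 1-based integers and
#' the original labels are kept so that files written back use them.
#'
#' @param u,v vectors of endpoint labels (coerced to character).
#' @param w positive edge weights, recycled to length of `u`; default 1.
#' @param isolated_labels optional extra node labels with no edges.
#' @return an object of class `gps_graph`.
#' @export
graph_from_edges <- function(u, v, w = 1, isolated_labels = character(0)) {
  u <- as.character(u); v <- as.character(v)
  if (length(u) != length(v)) stop("u and v must have equal length")
  w <- rep_len(as.numeric(w), length(u))
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive")
  if (any(u == v)) stop("self-loops are not allowed")
  labels <- unique(c(u, v, as.character(isolated_labels)))
  # numeric-looking label sets are ordered numerically for stable dense ids
  if (length(labels) > 0 && !anyNA(suppressWarnings(as.numeric(labels)))) {
    labels <- labels[order(as.numeric(labels))]
  } else {
    labels <- sort(labels)
  }
  ui <- match(u, labels); vi <- match(v, labels)
  a <- pmin(ui, vi); b <- pmax(ui, vi)
  key <- paste(a, b)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate undirected edge(s) collapsed (first weight kept)",
                    sum(dup)))
    a <- a[!dup]; b <- b[!dup]; w <- w[!dup]
  }
  new_graph(length(labels), cbind(a, b), w, labels)
}

#' @export
print.gps_graph <- function(x, ...) {
  cat(sprintf("gps_graph: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges
#' @param g a `gps_graph`.
#' @return integer count.
#' @export
n_nodes <- function(g) g$n

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

node_index <- function(g, v) {
  if (is.numeric(v) && all(v == as.integer(v)) && all(v >= 1) && all(v <= g$n) &&
      !any(as.character(v) %in% g$labels)) {
    return(as.integer(v))
  }
  idx <- match(as.character(v), g$labels)
  if (anyNA(idx)) {
    # fall back: dense index given numerically
    if (is.numeric(v) && all(v >= 1) && all(v <= g$n)) return(as.integer(v))
    stop(sprintf("unknown node: %s", paste(v[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Read an undirected edge list
#'
#' Parses a whitespace-separated edge list, one edge per line as
#' `u v` or `u v w` when `weighted = TRUE`. Lines starting with `#` are
#' skipped. Duplicate undirected edges are collapsed, keeping the first
#' weight, with a warning. Self-loops, malformed lines and non-positive
#' weights are errors that name the offending line.
#'
#' @param path file path.
#' @param weighted if `TRUE`, a third numeric column of positive weights is
#'   required.
#' @return a `gps_graph`.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  want <- if (weighted) 3L else 2L
  us <- character(length(lines)); vs <- character(length(lines))
  ws <- numeric(length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != want) {
      stop(sprintf("line %d: expected %d fields, got %d", lineno[i], want,
                   length(tok)))
    }
    if (tok[1] == tok[2]) stop(sprintf("line %d: self-loop '%s'", lineno[i], tok[1]))
    us[i] <- tok[1]; vs[i] <- tok[2]
    if (weighted) {
      w <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(w)) stop(sprintf("line %d: non-numeric weight '%s'", lineno[i], tok[3]))
      if (w <= 0) stop(sprintf("line %d: weight must be > 0, got %g", lineno[i], w))
      ws[i] <- w
    } else ws[i] <- 1
  }
  if (length(lines) == 0) return(new_graph(0L, NULL, numeric(0), character(0)))
  graph_from_edges(us, vs, ws)
}

#' Write an undirected edge list
#'
#' One line per edge, smaller-label endpoint first, rows in deterministic
#' order by dense node id. Weights are written when `weighted = TRUE`.
#'
#' @param g a `gps_graph`.
#' @param path output path.
#' @param weighted include the weight column.
#' @export
write_edge_list <- function(g, path, weighted = FALSE) {
  e <- g$edges
  if (nrow(e) > 0) {
    o <- order(e[, 1], e[, 2])
    e <- e[o, , drop = FALSE]
    w <- g$weights[o]
    lines <- if (weighted) {
      paste(g$labels[e[, 1]], g$labels[e[, 2]], format(w, trim = TRUE))
    } else {
      paste(g$labels[e[, 1]], g$labels[e[, 2]])
    }
  } else lines <- character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Node degree
#'
#' Unweighted degree: the number of neighbors of `v`, the row sum of the
#' adjacency indicator.
#'
#' @param g a `gps_graph`.
#' @param v node label or dense id; if missing, all degrees are returned in
#'   dense-id order.
#' @return non-negative integer(s).
#' @export
degree <- function(g, v) {
  if (missing(v)) return(vapply(g$adj, length, integer(1)))
  vapply(g$adj[node_index(g, v)], length, integer(1))
}

#' Graph Laplacian
#'
#' Returns the combinatorial Laplacian `D - A` or, with `normalized = TRUE`,
#' the symmetric normalized form `I - D^{-1/2} A D^{-1/2}`. The adjacency `A`
#' carries edge weights.
#'
#' @param g a `gps_graph`.
#' @param normalized logical; the normalized form requires minimum degree 1.
#' @return a dense symmetric n x n matrix.
#' @export
laplacian <- function(g, normalized = FALSE) {
  n <- g$n
  A <- matrix(0, n, n)
  if (n_edges(g) > 0) {
    A[g$edges] <- g$weights
    A[g$edges[, c(2, 1), drop = FALSE]] <- g$weights
  }
  d <- rowSums(A)
  if (!normalized) return(diag(d, n) - A)
  if (any(degree(g) == 0)) {
    stop("normalized Laplacian undefined: graph has an isolated node")
  }
  s <- 1 / sqrt(d)
  diag(1, n) - (s * A) %*% diag(s, n)
}

#' Power-law graph generator (preferential attachment)
#'
#' Grows a connected graph with a long-tailed degree distribution: start from
#' a triangle, then attach each arriving node to `m` distinct existing nodes
#' chosen with probability proportional to their current degree. With `m = 2`
#' the edge count is exactly `2 (n - 3) + 3`.
#'
#' @param n number of nodes, `n > m`.
#' @param m edges added per arriving node, `m >= 1`.
#' @param seed integer seed; the construction is bit-reproducible.
#' @return a `gps_graph` with labels `"1" .. "n"`.
#' @export
generate_power_law_graph <- function(n, m, seed) {
  if (m < 1) stop("m must be >= 1")
  if (n <= m) stop("need n > m")
  withr::with_seed(as.integer(seed), {
    n0 <- max(3L, m + 1L)
    # seed clique on the first n0 nodes (a triangle when m <= 2)
    init <- utils::combn(n0, 2)
    eu <- init[1, ]; ev <- init[2, ]
    deg <- integer(n)
    deg[seq_len(n0)] <- n0 - 1L
    # repeated-endpoint list for degree-proportional target choice
    targets <- c(eu, ev)
    if (n > n0) {
      for (new in (n0 + 1L):n) {
        chosen <- integer(0)
        while (length(chosen) < m) {
          pick <- targets[sample.int(length(targets), 1L)]
          if (!(pick %in% chosen)) chosen <- c(chosen, pick)
        }
        eu <- c(eu, chosen); ev <- c(ev, rep(new, m))
        targets <- c(targets, chosen, rep(new, m))
        deg[chosen] <- deg[chosen] + 1L
        deg[new] <- m
      }
    }
    a <- pmin(eu, ev); b <- pmax(eu, ev)
    new_graph(as.integer(n), cbind(a, b), rep(1, length(a)),
              as.character(seq_len(n)))
  })
}

#' Stochastic block model generator
#'
#' Planted-community random graph: node pairs inside a block are connected
#' independently with probability `p_in`, pairs across blocks with `p_out`.
#'
#' @param sizes integer vector of block sizes.
#' @param p_in,p_out connection probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return a list with elements `graph` (a `gps_graph`; isolated nodes are
#'   retained) and `labels` (integer block id per node, dense-id order).
#' @export
generate_sbm <- function(sizes, p_in, p_out, seed) {
  if (!(p_out >= 0 && p_in <= 1 && p_out < p_in)) {
    stop("require 0 <= p_out < p_in <= 1")
  }
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  withr::with_seed(as.integer(seed), {
    pairs <- utils::combn(n, 2)
    same <- block[pairs[1, ]] == block[pairs[2, ]]
    p <- ifelse(same, p_in, p_out)
    on <- stats::runif(ncol(pairs)) < p
    eu <- pairs[1, on]; ev <- pairs[2, on]
    g <- new_graph(as.integer(n), cbind(eu, ev), rep(1, length(eu)),
                   as.character(seq_len(n)))
    list(graph = g, labels = block)
  })
}

#' Degree-distribution diagnostics
#'
#' Summarizes the long-tail structure of a graph: the degree histogram, the
#' least-squares slope of the log-log degree distribution, and the tail
#' share — the fraction of edge endpoints incident to the top 1% highest-
#' degree nodes (at least one node). The slope is fit on a logarithmically
#' binned histogram (geometric bins of factor 2, count density per bin
#' against the geometric bin center), the standard estimator for heavy
#' tails, where a raw count-per-degree fit is flattened by the many
#' singleton counts in the tail. A slope needs at least two occupied bins;
#' otherwise it is `NA`. The tail share is the fraction of edges with at
#' least one endpoint among the top nodes, so a star's center scores 1.
#'
#' @param g a `gps_graph` with at least one edge.
#' @return a list of class `gps_degree_stats` with `histogram` (named count
#'   vector), `slope`, and `tail_share`.
#' @export
degree_distribution_stats <- function(g) {
  if (n_edges(g) == 0) stop("degree statistics need at least one edge")
  d <- degree(g)
  tab <- table(d)
  hist <- stats::setNames(as.integer(tab), names(tab))
  pos <- d[d > 0]
  slope <- NA_real_
  if (length(unique(pos)) >= 2) {
    brk <- 2^(0:ceiling(log2(max(pos))))
    bin <- findInterval(pos, brk)
    cnt <- tabulate(bin, nbins = length(brk) - 1)
    width <- diff(brk)
    ctr <- sqrt(brk[-length(brk)] * brk[-1])
    keep <- cnt > 0
    if (sum(keep) >= 2) {
      dens <- cnt[keep] / width[keep]
      fit <- stats::lm(log(dens) ~ log(ctr[keep]))
      slope <- unname(stats::coef(fit)[2])
    }
  }
  ntop <- max(1L, floor(0.01 * g$n))
  top <- order(d, decreasing = TRUE)[seq_len(ntop)]
  touched <- g$edges[, 1] %in% top | g$edges[, 2] %in% top
  tail_share <- mean(touched)
  structure(list(histogram = hist, slope = slope, tail_share = tail_share),
            class = "gps_degree_stats")
}

#' @export
print.gps_degree_stats <- function(x, ...) {
  cat(sprintf("degree stats: %d distinct degrees, tail slope %s, tail share %.4f\n",
              length(x$histogram),
              if (is.na(x$slope)) "NA" else sprintf("%.3f", x$slope),
              x$tail_share))
  invisible(x)
}
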