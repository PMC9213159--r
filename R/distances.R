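#' Breadth-first shortest-path distances
#'
#' Unweighted hop distances from a source node; unreachable nodes get `Inf`.
#'
#' @param g a `gps_graph`.
#' @param source node (label or dense id).
#' @return numeric vector of length `n` in dense-id order.
#' @export
bfs_distances <- function(g, source) {
  s <- node_index(g, source)
  dist <- rep(Inf, g$n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(g$adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Mean walk displacement from the source
#'
#' Average shortest-path distance from the walk's source over the nodes of a
#' walk (excluding the source position itself). Outward (depth-first-like,
#' small q) walks score higher than local (breadth-first-like, large q)
#' ones.
#'
#' @param g a `gps_graph`.
#' @param walk integer node sequence whose first element is the source.
#' @return non-negative scalar.
#' @export
walk_displacement <- function(g, walk) {
  if (length(walk) < 2) return(0)
  dist <- bfs_distances(g, walk[1])
  mean(dist[walk[-1]])
}
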