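# Hypergraph H(V, N): vertices with weights c(v), networks (hyperedges) as
# vertex subsets with costs c(n). Vertex ids are dense 1-based integers both
# internally and in the hMETIS-like file dialect.

#' Build a hypergraph
#'
#' @param n_vertices number of vertices.
#' @param nets list of integer vectors, each a non-empty subset of
#'   `1:n_vertices` (duplicates within a net are dropped).
#' @param vertex_weights positive weights `c(v)`, recycled; default 1.
#' @param net_costs positive costs `c(n)`, recycled; default 1.
#' @return an object of class `gps_hypergraph`.
#' @export
hypergraph <- function(n_vertices, nets, vertex_weights = 1, net_costs = 1) {
  n_vertices <- as.integer(n_vertices)
  nets <- lapply(nets, function(x) sort(unique(as.integer(x))))
  if (any(vapply(nets, length, integer(1)) == 0)) stop("every net must be non-empty")
  rng <- range(unlist(nets), na.rm = TRUE)
  if (length(unlist(nets)) > 0 && (rng[1] < 1 || rng[2] > n_vertices)) {
    stop("net vertex id out of range")
  }
  vw <- rep_len(as.numeric(vertex_weights), n_vertices)
  nc <- rep_len(as.numeric(net_costs), length(nets))
  if (any(vw <= 0) || any(nc <= 0)) stop("weights and costs must be > 0")
  structure(list(n_vertices = n_vertices, nets = nets,
                 vertex_weights = vw, net_costs = nc),
            class = "gps_hypergraph")
}

#' @export
print.gps_hypergraph <- function(x, ...) {
  cat(sprintf("gps_hypergraph: %d vertices, %d nets\n",
              x$n_vertices, length(x$nets)))
  invisible(x)
}

#' Read a hypergraph file
#'
#' hMETIS-like dialect: a header line `num_nets num_vertices`, then one line
#' of 1-based vertex ids per net. With `with_costs = TRUE` the first token of
#' each net line is the net cost.
#'
#' @param path file path.
#' @param with_costs whether net lines carry a leading cost column.
#' @return a `gps_hypergraph`.
#' @export
read_hypergraph <- function(path, with_costs = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*%", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty hypergraph file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) stop("line 1: header must be 'num_nets num_vertices'")
  m <- hdr[1]; nv <- hdr[2]
  if (length(lines) - 1 != m) {
    stop(sprintf("expected %d net lines, found %d", m, length(lines) - 1))
  }
  nets <- vector("list", m)
  costs <- rep(1, m)
  for (i in seq_len(m)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (with_costs) {
      costs[i] <- suppressWarnings(as.numeric(tok[1]))
      if (is.na(costs[i]) || costs[i] <= 0) {
        stop(sprintf("line %d: bad net cost", lineno[i + 1]))
      }
      tok <- tok[-1]
    }
    ids <- suppressWarnings(as.integer(tok))
    if (length(ids) == 0) stop(sprintf("line %d: empty net", lineno[i + 1]))
    if (anyNA(ids) || any(ids < 1) || any(ids > nv)) {
      stop(sprintf("line %d: vertex id out of range 1..%d", lineno[i + 1], nv))
    }
    nets[[i]] <- ids
  }
  hypergraph(nv, nets, net_costs = costs)
}

#' Write a hypergraph file
#'
#' @param h a `gps_hypergraph`.
#' @param path output path.
#' @param with_costs write a leading net-cost column.
#' @export
write_hypergraph <- function(h, path, with_costs = FALSE) {
  lines <- c(sprintf("%d %d", length(h$nets), h$n_vertices),
             vapply(seq_along(h$nets), function(i) {
               body <- paste(h$nets[[i]], collapse = " ")
               if (with_costs) paste(format(h$net_costs[i], trim = TRUE), body)
               else body
             }, character(1)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Random hypergraph generator
#'
#' Each net is a random vertex subset whose size is uniform on `size_range`,
#' and every vertex is guaranteed to belong to at least one net. When the
#' total slot capacity covers the vertex count, coverage is achieved within
#' the drawn sizes (vertices are dealt into net slots first, the remaining
#' slots filled uniformly), so net sizes are exactly as drawn; only when
#' the capacity falls short are the missing vertices appended to random
#' nets, growing them beyond the drawn size.
#'
#' @param n_vertices,n_nets counts.
#' @param size_range integer `c(min, max)` net size, `max <= n_vertices`.
#' @param seed integer seed.
#' @return a `gps_hypergraph`.
#' @export
generate_hypergraph <- function(n_vertices, n_nets, size_range, seed) {
  lo <- as.integer(size_range[1]); hi <- as.integer(size_range[2])
  if (lo < 1 || hi < lo || hi > n_vertices) stop("infeasible net size range")
  withr::with_seed(as.integer(seed), {
    sizes <- if (hi > lo) sample(lo:hi, n_nets, replace = TRUE) else rep(lo, n_nets)
    nets <- lapply(sizes, function(s) integer(0))
    if (sum(sizes) >= n_vertices) {
      # deal every vertex into some net with free capacity, then fill the
      # leftover slots with distinct extra vertices per net
      for (v in sample.int(n_vertices)) {
        open <- which(lengths(nets) < sizes)
        j <- open[sample.int(length(open), 1)]
        nets[[j]] <- c(nets[[j]], v)
      }
      for (j in seq_len(n_nets)) {
        need <- sizes[j] - length(nets[[j]])
        if (need > 0) {
          avail <- setdiff(seq_len(n_vertices), nets[[j]])
          nets[[j]] <- c(nets[[j]], avail[sample.int(length(avail), need)])
        }
      }
    } else {
      nets <- lapply(sizes, function(s) sample.int(n_vertices, s))
      missing <- setdiff(seq_len(n_vertices), unique(unlist(nets)))
      for (v in missing) {
        j <- sample.int(n_nets, 1)
        nets[[j]] <- c(nets[[j]], v)
      }
    }
    hypergraph(n_vertices, nets)
  })
}

#' Vertex overdegree
#'
#' The number of nets containing a vertex (the column sum of the incidence
#' indicator).
#'
#' @param h a `gps_hypergraph`.
#' @param v vertex id (1-based); if missing, all overdegrees.
#' @return non-negative integer(s).
#' @export
overdegree <- function(h, v) {
  cnt <- tabulate(unlist(h$nets), nbins = h$n_vertices)
  if (missing(v)) return(cnt)
  v <- as.integer(v)
  if (any(v < 1 | v > h$n_vertices)) stop("unknown vertex")
  cnt[v]
}

# Dense incidence matrix (vertices x nets), used by partition costs.
incidence_matrix <- function(h) {
  m <- length(h$nets)
  M <- matrix(FALSE, h$n_vertices, m)
  for (j in seq_len(m)) M[h$nets[[j]], j] <- TRUE
  M
}
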