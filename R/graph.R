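#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `round(density * n(n-1)/2)` strongest off-diagonal weights
#' (round-half-up) and zeroes the rest; retained edges keep their weights.
#' Ties straddling the cutoff are broken deterministically by node-index
#' order (lowest pair first) and reported with a warning.
#'
#' @param c A [connectivity_matrix()] or plain symmetric matrix.
#' @param density Fraction of possible edges to retain, in `(0, 1]`
#'   (default 0.20).
#' @param binarize Set retained weights to 1 instead of keeping them
#'   (default `FALSE`; the modularity and efficiency formulas used here
#'   are weighted).
#' @return A `thresholded_graph`: list with `adjacency` (zero diagonal),
#'   `density` (realised), `n_edges` and `labels`.
#' @export
proportional_threshold <- function(c, density = 0.20, binarize = FALSE) {
  stopifnot(is.matrix(c), nrow(c) == ncol(c))
  if (!(density > 0 && density <= 1)) {
    stop("`density` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(c)
  labels <- rownames(c)
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(n))
  pairs <- upper_pairs(n)
  w <- c[pairs]
  n_possible <- nrow(pairs)
  n_keep <- as.integer(round_half_up(density * n_possible))
  n_keep <- max(1L, min(n_keep, n_possible))
  ord <- order(-w, pairs[, 1L], pairs[, 2L])    # strongest first, index tie-break
  if (n_keep < n_possible && w[ord[n_keep]] == w[ord[n_keep + 1L]]) {
    warning("ties at the threshold cutoff broken by node-index order")
  }
  sel <- ord[seq_len(n_keep)]
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  adj[pairs[sel, , drop = FALSE]] <- if (binarize) 1 else w[sel]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = n_keep / n_possible,
                 n_edges = n_keep, labels = labels),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

as_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) g$adjacency
  else if (is.matrix(g)) g
  else stop("expected a thresholded_graph or adjacency matrix", call. = FALSE)
}

#' All-pairs shortest path lengths (Floyd-Warshall)
#'
#' Edge lengths are the inverse of the connection weights (the standard
#' transform for PLV-type affinity weights: stronger coupling = shorter
#' path), absent edges are infinitely long, and the whole-network distance
#' matrix is computed with the Floyd-Warshall recursion.
#'
#' @param g A `thresholded_graph` or nonnegative symmetric adjacency
#'   matrix (zeros = absent edges).
#' @return An n x n matrix of shortest path lengths; `Inf` for
#'   unreachable pairs, 0 on the diagonal.
#' @export
shortest_paths <- function(g) {
  a <- as_adjacency(g)
  if (any(a < 0)) stop("negative weights are not allowed", call. = FALSE)
  len <- ifelse(a > 0, 1 / a, Inf)
  diag(len) <- 0
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) {
    through_k <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, through_k)
  }
  dimnames(d) <- dimnames(a)
  d
}

#' Global efficiency of a weighted graph
#'
#' The average inverse shortest path length over all ordered node pairs,
#' `E = 1/(n(n-1)) * sum_{i != j} 1/d_ij`, with `1/Inf = 0` for
#' unreachable pairs.  Values lie in `[0, 1]` when all weights are at
#' most 1 (true for PLV graphs).
#'
#' @inheritParams shortest_paths
#' @return A scalar efficiency.
#' @export
global_efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2L) stop("global efficiency needs at least two nodes", call. = FALSE)
  d <- shortest_paths(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Routing matrix: inverse shortest path lengths with a unit diagonal
#'
#' Off-diagonal entries are `1/d_ij` (0 for unreachable pairs); the
#' diagonal is 1 by convention.
#'
#' @inheritParams shortest_paths
#' @return An n x n `routing_matrix`.
#' @export
routing_matrix <- function(g) {
  d <- shortest_paths(g)
  r <- 1 / d
  diag(r) <- 1
  structure(r, class = c("routing_matrix", "matrix", "array"))
}

#' Maximum routing efficiency between two node sets
#'
#' The maximum inverse shortest path length over all (core node, extended
#' node) pairs -- the single best communication channel between the two
#' subsystems.
#'
#' @param r A [routing_matrix()] (or the graph to derive it from).
#' @param sets A list with non-empty disjoint elements `core` and
#'   `extended`, given as labels (matched against dimnames) or integer
#'   indices.
#' @return A scalar in `[0, 1]` for PLV-weighted graphs; 0 when the sets
#'   lie in different components.
#' @export
routing_efficiency <- function(r, sets) {
  if (!inherits(r, "routing_matrix")) r <- routing_matrix(r)
  core <- resolve_nodes(r, sets$core)
  ext <- resolve_nodes(r, sets$extended)
  if (!length(core) || !length(ext)) {
    stop("both node sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(core, ext))) {
    stop("core and extended sets must be disjoint", call. = FALSE)
  }
  max(r[core, ext, drop = FALSE])
}

resolve_nodes <- function(m, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, rownames(m))
    if (anyNA(idx)) {
      stop("unknown node label(s): ",
           paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    idx
  } else {
    as.integer(nodes)
  }
}

#' Evaluate the weighted modularity of a given partition
#'
#' Direct evaluation of
#' `Q = 1/(2m) * sum_ij (A_ij - gamma * k_i k_j / (2m)) * delta(c_i, c_j)`
#' with weighted degrees `k` and total weight `2m = sum(A)`.
#'
#' @param g A `thresholded_graph` or adjacency matrix.
#' @param membership Community assignment, one entry per node.
#' @param gamma Resolution parameter (default 1).
#' @return The modularity value (in `[-1, 1]`).
#' @export
modularity_value <- function(g, membership, gamma = 1) {
  a <- as_adjacency(g)
  stopifnot(length(membership) == nrow(a))
  m2 <- sum(a)
  if (m2 <= 0) stop("graph has no edges", call. = FALSE)
  k <- rowSums(a)
  same <- outer(membership, membership, "==")
  sum((a - gamma * outer(k, k) / m2) * same) / m2
}

#' Community detection by weighted Louvain modularity maximisation
#'
#' Greedy two-phase Louvain optimisation of the weighted modularity, run
#' `n_restarts` times with distinct random node orders; the partition with
#' the highest directly-evaluated Q is returned.  Fixed `seed` and
#' `n_restarts` give a deterministic result.
#'
#' @param g A `thresholded_graph` or nonnegative adjacency matrix with at
#'   least one edge.
#' @param gamma Resolution parameter (default 1).
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Integer seed for the restart orders.
#' @return A `partition_result`: list with `q` (modularity of the returned
#'   partition, by direct formula evaluation), `communities` (integer
#'   vector, names = node labels), `n_restarts` and `seed`.
#' @export
graph_modularity <- function(g, gamma = 1, n_restarts = 100, seed = 1L) {
  a <- as_adjacency(g)
  if (any(a < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (sum(a) <= 0) stop("graph has no edges", call. = FALSE)
  n <- nrow(a)
  best_q <- -Inf
  best_memb <- seq_len(n)
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      memb <- louvain_once(a, gamma)
      q <- modularity_value(a, memb, gamma)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_memb <- memb
      }
    }
  })
  communities <- match(best_memb, unique(best_memb))
  names(communities) <- rownames(a)
  structure(list(q = best_q, communities = communities,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> Q = %.4f, %d communities (%d restarts)\n",
              x$q, length(unique(x$communities)), x$n_restarts))
  invisible(x)
}

# One full Louvain run (local moving + aggregation until stable), using
# the caller's RNG stream for the node orders.
louvain_once <- function(a, gamma) {
  n0 <- nrow(a)
  node_comm <- seq_len(n0)     # original node -> community label
  b <- a
  repeat {
    memb <- louvain_local_moving(b, gamma)
    memb <- match(memb, unique(memb))
    if (length(unique(memb)) == nrow(b)) break
    node_comm <- memb[node_comm]
    # aggregate: super-node adjacency (internal weight lands on the diagonal)
    s <- length(unique(memb))
    agg <- rowsum(t(rowsum(b, memb)), memb)
    b <- as.matrix(agg)
    if (s == 1L) break
  }
  node_comm
}

louvain_local_moving <- function(b, gamma) {
  n <- nrow(b)
  comm <- seq_len(n)
  m2 <- sum(b)
  k <- rowSums(b)
  tot <- k                      # community total degree (index = community id)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      li <- b[i, ]
      li[i] <- 0
      wc <- rowsum(li, comm)    # links from i to each community
      cands <- as.integer(rownames(wc))
      tot[ci] <- tot[ci] - k[i]
      gain <- wc[, 1L] - gamma * k[i] * tot[cands] / m2
      stay <- match(ci, cands)
      best <- which.max(gain)
      if (gain[best] > gain[stay] + 1e-12) {
        comm[i] <- cands[best]
        improved <- TRUE
      }
      tot[comm[i]] <- tot[comm[i]] + k[i]
    }
  }
  comm
}

#' Destrieux-atlas parcel labels and face-network subsystem assignment
#'
#' Returns the bundled 148-parcel table (74 Destrieux regions per
#' hemisphere) with a `system` column assigning each parcel to the core
#' face-processing system (fusiform, inferior/middle occipital and
#' superior temporal sulcus regions), the extended system
#' (superior/inferior frontal gyri, temporal pole, insula and secondary
#' sensorimotor regions) or `other`.  The assignment is a curated reading
#' of the canonical core/extended region lists and is meant to be edited:
#' pass any two-column `parcel_label, system` CSV to [read_node_sets()] to
#' override it.
#'
#' @param path CSV file to read; defaults to the bundled table.
#' @return Data frame with columns `parcel_label` and `system`.
#' @export
destrieux_face_systems <- function(path = system.file("extdata",
                                                      "destrieux_face_systems.csv",
                                                      package = "alphanet")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a core/extended node-set assignment
#'
#' @param path Two-column CSV (`parcel_label`, `system`), where `system`
#'   is `core`, `extended` or `other`.
#' @return A list with character elements `core` and `extended`, suitable
#'   for [routing_efficiency()].
#' @export
read_node_sets <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parcel_label", "system") %in% names(tab)))
  sets <- list(core = tab$parcel_label[tab$system == "core"],
               extended = tab$parcel_label[tab$system == "extended"])
  if (!length(sets$core) || !length(sets$extended)) {
    stop("node-set file must assign at least one core and one extended parcel",
         call. = FALSE)
  }
  if (length(intersect(sets$core, sets$extended))) {
    stop("core and extended sets overlap", call. = FALSE)
  }
  sets
}
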