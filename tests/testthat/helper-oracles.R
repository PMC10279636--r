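# Independent oracles used across the suite.

# All-pairs shortest path lengths by exhaustive simple-path enumeration
# (edge length = 1/weight).  Prunes a prefix only when it is strictly worse
# than a path already found to the same vertex, which never discards an
# optimal-prefix path.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  len <- ifelse(adj > 0, 1 / adj, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    visit <- function(i, cost, used) {
      for (j in seq_len(n)) {
        if (used[j] || !is.finite(len[i, j])) next
        cj <- cost + len[i, j]
        if (cj > best[s, j]) next
        best[s, j] <<- cj
        used[j] <- TRUE
        visit(j, cj, used)
        used[j] <- FALSE
      }
    }
    used <- rep(FALSE, n)
    used[s] <- TRUE
    visit(s, 0, used)
  }
  best
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_shortest_paths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_routing_efficiency <- function(adj, core, ext) {
  d <- oracle_shortest_paths(adj)
  max(1 / d[core, ext, drop = FALSE])
}

# All set partitions of n elements as restricted-growth membership vectors.
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(adj, gamma = 1) {
  parts <- set_partitions(nrow(adj))
  qs <- vapply(parts, function(p) modularity_value(adj, p, gamma), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# Random symmetric weighted graph (weights in (0, 1], zero diagonal).
random_adjacency <- function(n, p_edge = 0.6) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  on <- ut & matrix(stats::runif(n * n) < p_edge, n, n)
  a[on] <- stats::runif(sum(on), 0.05, 1)
  a + t(a)
}

adjusted_rand <- function(x, y) mclust::adjustedRandIndex(x, y)

# stack single-epoch arrays (1 x nodes x samples) into one epoch_array data cube
abind_epochs <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(length(lst), d[2], d[3]))
  for (i in seq_along(lst)) out[i, , ] <- lst[[i]][1, , ]
  out
}
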