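mat4 <- function() {
  # 4 nodes, upper-triangle weights 0.9, 0.8, 0.7, 0.3, 0.2, 0.1
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.9; m[1, 3] <- 0.8; m[1, 4] <- 0.7
  m[2, 3] <- 0.3; m[2, 4] <- 0.2; m[3, 4] <- 0.1
  m <- m + t(m); diag(m) <- 1
  m
}

test_that("proportional thresholding keeps the strongest edges, weighted", {
  g <- proportional_threshold(mat4(), density = 0.5)
  expect_equal(g$n_edges, 3L)
  expect_equal(sort(g$adjacency[upper.tri(g$adjacency)], decreasing = TRUE)[1:3],
               c(0.9, 0.8, 0.7))
  expect_equal(sum(g$adjacency[upper.tri(g$adjacency)] > 0), 3)
  expect_true(all(diag(g$adjacency) == 0))

  gd <- proportional_threshold(mat4(), density = 1)
  expect_equal(gd$adjacency, mat4() - diag(4), ignore_attr = TRUE)

  set.seed(1)
  m <- matrix(runif(148^2), 148)
  m <- (m + t(m)) / 2; diag(m) <- 1
  g148 <- proportional_threshold(m, density = 0.2)
  expect_equal(g148$n_edges, 2176L)   # round-half-up of 0.2 * 148 * 147 / 2

  expect_error(proportional_threshold(mat4(), density = 0), "0, 1")
})

test_that("threshold ties at the cutoff are broken deterministically with a warning", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.1)
  m <- m + t(m); diag(m) <- 1
  expect_warning(g1 <- proportional_threshold(m, density = 0.5), "ties")
  expect_warning(g2 <- proportional_threshold(m, density = 0.5), "ties")
  expect_identical(g1$adjacency, g2$adjacency)
  expect_equal(g1$n_edges, 3L)
})

test_that("Floyd-Warshall distances match hand cases and the enumeration oracle", {
  # unit-weight path 1-2-3
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- 1; a <- a + t(a)
  d <- shortest_paths(a)
  expect_equal(d[1, 3], 2)

  # triangle: direct weight-1 edge beats two weight-0.5 hops (2 + 2)
  tr <- matrix(0, 3, 3)
  tr[1, 2] <- 1; tr[1, 3] <- 0.5; tr[2, 3] <- 0.5
  tr <- tr + t(tr)
  expect_equal(shortest_paths(tr)[1, 2], 1)

  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p_edge = 0.5)
    expect_equal(shortest_paths(adj), oracle_shortest_paths(adj),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  neg <- a; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(shortest_paths(neg), "negative")
})

test_that("global efficiency matches closed forms and bounds", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_efficiency(k4), 1)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(global_efficiency(path3), 5 / 6)

  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_error(global_efficiency(matrix(0, 1, 1)), "two nodes")

  # weights <= 1 keep efficiency in [0, 1]
  set.seed(23)
  for (i in 1:10) {
    e <- global_efficiency(random_adjacency(6))
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("routing matrix inverts path lengths with a unit diagonal", {
  chain <- matrix(0, 4, 4)
  chain[1, 2] <- chain[2, 3] <- chain[3, 4] <- 1
  chain <- chain + t(chain)
  r <- routing_matrix(chain)
  expect_equal(r[1, 4], 1 / 3)
  expect_true(all(diag(r) == 1))

  two <- matrix(0, 4, 4); two[1, 2] <- two[3, 4] <- 1; two <- two + t(two)
  r2 <- routing_matrix(two)
  expect_equal(r2[1, 3], 0)
  expect_equal(r2[2, 4], 0)
})

test_that("routing efficiency is the best core-extended channel", {
  chain <- matrix(0, 4, 4)
  chain[1, 2] <- 0.8; chain[2, 3] <- 0.9; chain[3, 4] <- 0.4
  chain <- chain + t(chain)
  sets <- list(core = c(1, 2), extended = c(3, 4))
  # best cross pair is 2-3 with one direct edge of weight 0.9
  expect_equal(routing_efficiency(routing_matrix(chain), sets), 0.9)

  two <- matrix(0, 4, 4); two[1, 2] <- two[3, 4] <- 1; two <- two + t(two)
  expect_equal(routing_efficiency(two, sets), 0)

  expect_error(routing_efficiency(chain, list(core = integer(0), extended = 3)),
               "non-empty")
  expect_error(routing_efficiency(chain, list(core = c(1, 3), extended = c(3, 4))),
               "disjoint")

  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    adj <- random_adjacency(n, p_edge = 0.4)
    core <- 1:2; ext <- 3:4
    expect_equal(routing_efficiency(adj, list(core = core, extended = ext)),
                 oracle_routing_efficiency(adj, core, ext), tolerance = 1e-12)
  }
})

test_that("efficiencies never decrease when an edge is added", {
  set.seed(31)
  sets <- list(core = 1:2, extended = 3:4)
  for (i in 1:20) {
    adj <- random_adjacency(7, p_edge = 0.3)
    off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(off)) next
    pick <- off[sample(nrow(off), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    expect_gte(global_efficiency(adj2), global_efficiency(adj) - 1e-12)
    expect_gte(routing_efficiency(adj2, sets),
               routing_efficiency(adj, sets) - 1e-12)
  }
})

test_that("modularity evaluation and Louvain search behave on canonical graphs", {
  # the single-community partition has identically zero modularity
  set.seed(37)
  for (i in 1:5) {
    adj <- random_adjacency(6)
    expect_lt(abs(modularity_value(adj, rep(1, 6))), 1e-12)
  }

  # two disconnected 3-cliques: Q = 0.5 at the clique partition
  cl <- matrix(0, 6, 6)
  cl[1:3, 1:3] <- 1; cl[4:6, 4:6] <- 1; diag(cl) <- 0
  res <- graph_modularity(cl, n_restarts = 10, seed = 1)
  expect_equal(res$q, 0.5, tolerance = 1e-12)
  expect_equal(adjusted_rand(res$communities, rep(1:2, each = 3)), 1)

  # reported q always equals direct formula evaluation
  expect_equal(res$q, modularity_value(cl, res$communities), tolerance = 1e-12)
  adj <- random_adjacency(8)
  r2 <- graph_modularity(adj, n_restarts = 25, seed = 3)
  expect_equal(r2$q, modularity_value(adj, r2$communities), tolerance = 1e-12)

  # determinism
  r3 <- graph_modularity(adj, n_restarts = 25, seed = 3)
  expect_identical(r2, r3)

  expect_error(graph_modularity(matrix(0, 3, 3)), "no edges")
})

test_that("Louvain comes within 5% of the exhaustive optimum on small graphs", {
  set.seed(41)
  ok <- logical(20)
  for (i in seq_along(ok)) {
    n <- sample(5:7, 1)
    adj <- random_adjacency(n, p_edge = 0.5)
    if (sum(adj) == 0) { ok[i] <- TRUE; next }
    opt <- oracle_best_modularity(adj)
    got <- graph_modularity(adj, n_restarts = 20, seed = i)$q
    ok[i] <- got >= 0.95 * opt$q - 1e-12 || opt$q <= 0
  }
  expect_gte(mean(ok), 0.95)
})

test_that("Louvain agrees with an independent community-detection library", {
  skip_if_not_installed("igraph")
  set.seed(43)
  for (i in 1:5) {
    adj <- random_adjacency(12, p_edge = 0.4)
    q_mine <- graph_modularity(adj, n_restarts = 50, seed = i)$q
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              weighted = TRUE)
    q_ig <- max(replicate(10, igraph::modularity(
      igraph::cluster_louvain(gr))))
    expect_gte(q_mine, q_ig - 0.02)
  }
})

test_that("the bundled atlas table defines 148 parcels with disjoint systems", {
  atlas <- destrieux_face_systems()
  expect_equal(nrow(atlas), 148)
  expect_false(anyDuplicated(atlas$parcel_label) > 0)
  sets <- read_node_sets(system.file("extdata", "destrieux_face_systems.csv",
                                     package = "alphanet"))
  expect_gt(length(sets$core), 0)
  expect_gt(length(sets$extended), 0)
  expect_length(intersect(sets$core, sets$extended), 0)
})
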