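test_that("degree, clustering and path length are exact on canonical graphs", {
  k3 <- net_k3()
  p3 <- net_p3()
  expect_equal(node_degree(k3), rep(3L - 1L, 3))
  expect_equal(node_clustering(k3), rep(1, 3))
  expect_equal(nodal_path_length(k3), rep(1, 3))
  expect_equal(node_clustering(p3)[2], 0)          # centre: open triad
  expect_equal(node_clustering(p3)[c(1, 3)], c(-1, -1))  # degree-1 sentinel
  expect_equal(nodal_path_length(p3), c(1.5, 1, 1.5))
  empty <- binary_network(matrix(0L, 4, 4))
  expect_equal(node_degree(empty), rep(0L, 4))
  expect_equal(node_clustering(empty), rep(-1, 4))
  expect_equal(nodal_path_length(empty), rep(-1, 4))
  k4 <- binary_network(1L - diag(4L))
  expect_equal(node_degree(k4), rep(3L, 4))
})

test_that("all metrics agree with brute-force oracles on 100 random graphs", {
  for (s in 1:100) {
    n <- sample(5:30, 1)
    net <- random_net(n, runif(1, 0.1, 0.5), seed = 1000 + s)
    adj <- net$adjacency
    expect_equal(node_degree(net), as.integer(colSums(adj)))
    expect_equal(node_clustering(net), oracle_clustering(adj))
    expect_equal(nodal_path_length(net), oracle_path_length(adj))
    expect_equal(global_efficiency(net), oracle_efficiency(adj))
    expect_equal(length(giant_component(net)), oracle_gc_size(adj))
    # information centrality against the oracle efficiency route
    e0 <- oracle_efficiency(adj, n)
    ic_oracle <- sapply(seq_len(n), function(i)
      100 * (oracle_efficiency(adj[-i, -i, drop = FALSE], n) - e0) / e0)
    expect_equal(information_centrality(net), ic_oracle)
  }
})

test_that("efficiency follows the ordered-pair formula on P3 and K3", {
  expect_equal(global_efficiency(net_k3(), normalization_n = 3), 1)
  expect_equal(global_efficiency(net_p3(), normalization_n = 3), 5 / 6)
  expect_equal(global_efficiency(binary_network(matrix(0L, 3, 3))), 0)
})

test_that("information centrality: K3 removal, isolated nodes, equivariance", {
  # K3 plus one isolated node: removing a triangle vertex
  adj <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3)))
  net <- binary_network(adj)
  ic <- information_centrality(net)
  # fixed denominator n = 4: E = 6/12; remove vertex -> 2/12
  expect_equal(ic[1], 100 * (2 / 12 - 6 / 12) / (6 / 12))
  expect_equal(ic[4], 0)   # isolated node: exactly zero
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  net_p <- binary_network(adj[perm, perm])
  expect_equal(information_centrality(net_p), ic[perm])
  # undefined when the graph has no edges at all
  expect_error(information_centrality(binary_network(matrix(0L, 3, 3))),
               "undefined")
})

test_that("giant component ties resolve to the smallest parcel id", {
  # two triangles of equal size + isolated node
  adj <- adj_from_edges(7, list(c(1, 2), c(1, 3), c(2, 3),
                                c(4, 5), c(4, 6), c(5, 6)))
  net <- binary_network(adj)
  gc <- giant_component(net)
  expect_length(gc, 3)
  expect_equal(sort(gc), 1:3)
  # connected graph: everything
  expect_length(giant_component(net_k3()), 3)
})

test_that("rewired nulls preserve the degree sequence exactly", {
  net <- random_net(40, 0.15, seed = 77)
  sw <- small_world_summary(net, n_nulls = 5, seed = 3)
  expect_equal(sw$delta, sw$gamma / sw$lambda)
  # degree preservation checked through the generator directly
  g2 <- lesionnet:::.rewired_null(net)
  expect_equal(sort(node_degree(g2)), sort(node_degree(net)))
})

test_that("self-normalisation yields unit small-world indices", {
  net <- net_k3()
  # a 3-clique cannot be rewired into anything else, so nulls equal the net
  adj <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                                c(4, 5)))
  net <- binary_network(adj)
  gcm <- giant_component(net)
  L_net <- mean(nodal_path_length(net)[gcm])
  C_net <- mean(node_clustering(net)[node_degree(net) >= 2])
  expect_equal(small_world_index(C_net / C_net, L_net / L_net), 1)
})

test_that("lattices are small-world, matched random graphs are not", {
  set.seed(14)
  ring <- igraph::sample_smallworld(1, 100, 3, p = 0.05)
  bn <- binary_network(as.matrix(igraph::as_adjacency_matrix(ring)))
  sw <- small_world_summary(bn, n_nulls = 20, seed = 2)
  expect_gt(sw$delta, 1.5)
  deltas <- sapply(1:3, function(s) {
    er <- make_null_graph("random", 100, igraph::gsize(ring), seed = 30 + s)
    small_world_summary(er, n_nulls = 20, seed = s)$delta
  })
  expect_gt(mean(deltas), 0.85)
  expect_lt(mean(deltas), 1.15)
})

test_that("hub table ranks by degree with alphabetical tie-break", {
  at <- toy_atlas(2)
  adj <- adj_from_edges(8, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                c(5, 6)))
  net <- binary_network(adj, parcel_ids = at$id)
  tab <- hub_table(node_metrics(net, at), at)
  expect_equal(names(tab)[1:6],
               c("side", "abbreviation", "degree", "clustering",
                 "path_length", "information_centrality"))
  expect_equal(tab$degree, sort(tab$degree, decreasing = TRUE))
  expect_equal(tab$degree[1], max(node_degree(net)))
  ties <- tab[tab$degree == 1, ]
  expect_equal(ties$abbreviation, sort(ties$abbreviation))
  # degree-0 rows carry the sentinel triple
  zero <- tab[tab$degree == 0, ]
  expect_true(all(zero$clustering == -1))
  expect_true(all(zero$path_length == -1))
  expect_true(all(zero$information_centrality == 0))
})
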