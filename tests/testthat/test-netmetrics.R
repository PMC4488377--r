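# Distance transform, betweenness centrality, degree metrics and
# randomization nulls.

test_that("weights map to reciprocal distances with Inf for non-positive", {
  m <- connectivity_matrix(matrix(c(0, 2, 0, -1,
                                    1, 0, 0.5, 0,
                                    0, 0, 0, 4,
                                    3, 0, 0, 0), 4, 4, byrow = TRUE),
                           kind = "ppi_z_group")
  d <- weights_to_distances(m)
  expect_equal(d[1, 2], 0.5)
  expect_equal(d[2, 3], 2)
  expect_equal(d[1, 3], Inf)   # zero weight
  expect_equal(d[1, 4], Inf)   # negative weight
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
})

test_that("betweenness matches hand-computable topologies", {
  # 3-node chain A->B->C: B carries the single interior path
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  d[1, 2] <- 1; d[2, 3] <- 1
  expect_equal(unname(betweenness_centrality(d)), c(0, 1, 0))

  # 5-node star: all paths go through the hub, raw BC = (N-1)(N-2)
  star <- make_planted_hub_network(5, 3, on_weight = 1, off_weight = 0)
  bc <- betweenness_centrality(weights_to_distances(star))
  expect_equal(unname(bc), c(0, 0, 12, 0, 0))
  expect_equal(unname(betweenness_centrality(weights_to_distances(star),
                                             normalized = TRUE)),
               c(0, 0, 1, 0, 0))

  # fewer than three nodes: no interior vertices
  expect_equal(unname(betweenness_centrality(matrix(c(0, 1, 1, 0), 2))),
               c(0, 0))
})

test_that("betweenness equals exhaustive path enumeration on random digraphs", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    w <- random_weight_matrix(n)
    d <- weights_to_distances(w)
    expect_equal(unname(betweenness_centrality(d)),
                 brute_force_betweenness(d),
                 tolerance = 1e-10)
  }
  # including graphs with forced ties (unit weights)
  for (i in 1:20) {
    d <- matrix(ifelse(runif(36) < 0.4, 1, Inf), 6, 6)
    diag(d) <- 0
    expect_equal(unname(betweenness_centrality(d)),
                 brute_force_betweenness(d),
                 tolerance = 1e-10)
  }
})

test_that("betweenness agrees with igraph on weighted digraphs", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (i in 1:20) {
    w <- random_weight_matrix(7)
    d <- weights_to_distances(w)
    adj <- ifelse(is.finite(d), d, 0)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(unname(betweenness_centrality(d)),
                 unname(igraph::betweenness(g, directed = TRUE)),
                 tolerance = 1e-9)
  }
})

test_that("scaling all weights leaves betweenness unchanged", {
  set.seed(13)
  w <- random_weight_matrix(8)
  d1 <- weights_to_distances(w)
  d2 <- weights_to_distances(w * 2)
  expect_equal(betweenness_centrality(d1), betweenness_centrality(d2))
})

test_that("strengthening a node's edges never decreases its betweenness", {
  set.seed(14)
  for (i in 1:10) {
    w <- random_weight_matrix(6, p_absent = 0.2)
    v <- sample(6, 1)
    w2 <- w
    w2[v, ] <- w2[v, ] * 3
    w2[, v] <- w2[, v] * 3
    diag(w2) <- 0
    bc1 <- betweenness_centrality(weights_to_distances(w))
    bc2 <- betweenness_centrality(weights_to_distances(w2))
    expect_gte(bc2[v], bc1[v] - 1e-10)
  }
})

test_that("degree metrics count in, out and total connections", {
  full <- connectivity_matrix(matrix(1, 10, 10) - diag(10),
                              kind = "binary_anatomy")
  dm <- degree_metrics(full)
  expect_true(all(dm$degree == 18))
  expect_true(all(dm$outdegree_proportion == 0.5))

  empty <- connectivity_matrix(matrix(0, 4, 4), kind = "binary_anatomy")
  dm0 <- degree_metrics(empty)
  expect_true(all(dm0$degree == 0))
  expect_true(all(dm0$outdegree_proportion == 0))

  one <- matrix(0, 3, 3); one[1, 2] <- 1
  dm1 <- degree_metrics(connectivity_matrix(one, kind = "binary_anatomy"))
  expect_equal(dm1$outdegree, c(1, 0, 0))
  expect_equal(dm1$indegree, c(0, 1, 0))
  expect_equal(dm1$outdegree_proportion, c(1, 0, 0))

  expect_error(degree_metrics(matrix(2, 3, 3)), "binary")
})

test_that("weighted null finds a planted hub and respects exchangeability", {
  net <- make_planted_hub_network(10, 4, on_weight = 2, off_weight = 0.1)
  rep <- randomization_null_weighted(net, n_rand = 5000, rng_seed = 7)
  expect_lt(rep$nodes$p_value[4], 0.05)
  expect_true(all(rep$nodes$p_value >= 0 & rep$nodes$p_value <= 1))

  # constant weights: degenerate null, all p = 1 by convention
  const <- connectivity_matrix(matrix(1, 5, 5) - diag(5), kind = "ppi_z_group")
  expect_warning(repc <- randomization_null_weighted(const, n_rand = 200),
                 "degenerate")
  expect_true(all(repc$nodes$p_value == 1))

  # doubling the weights leaves every p unchanged (paths rank identically)
  rep2 <- randomization_null_weighted(
    connectivity_matrix(unclass(net) * 2, kind = "ppi_z_group"),
    n_rand = 2000, rng_seed = 11)
  rep1 <- randomization_null_weighted(net, n_rand = 2000, rng_seed = 11)
  expect_equal(rep1$nodes$p_value, rep2$nodes$p_value)
})

test_that("binary null preserves the edge count in every draw and flags hubs", {
  set.seed(15)
  # star digraph: all edges incident to node 1
  w <- matrix(0, 10, 10)
  w[1, 2:10] <- 1; w[2:10, 1] <- 1
  star <- connectivity_matrix(w, kind = "binarized_ppi")
  rep <- randomization_null_binary(star, n_rand = 5000, rng_seed = 3)
  expect_lt(rep$nodes$p_degree[1], 0.01)
  # conservation: pooled degree null sums to 2E per draw
  expect_equal(sum(rep$null_degree), 5000 * 2 * sum(w))

  expect_warning(
    randomization_null_binary(connectivity_matrix(matrix(0, 4, 4),
                                                  kind = "binarized_ppi"),
                              n_rand = 200),
    "degenerate")
})

test_that("anatomy betweenness validates its input", {
  loop <- matrix(0, 4, 4); diag(loop) <- 1
  expect_error(anatomy_betweenness(loop), "self-connections")
  expect_error(anatomy_betweenness(matrix(2, 3, 3) - 2 * diag(3)), "binary")

  # toy chain anatomy: interior nodes mediate, endpoints do not
  chain <- matrix(0, 4, 4)
  chain[cbind(1:3, 2:4)] <- 1
  rep <- anatomy_betweenness(connectivity_matrix(chain,
                                                 kind = "binary_anatomy"),
                             n_rand = 500, rng_seed = 1)
  bc <- rep$nodes$betweenness
  expect_true(all(bc[2:3] > 0))
  expect_equal(bc[c(1, 4)], c(0, 0))
})

test_that("pooled null p-values are calibrated for exchangeable weights", {
  set.seed(16)
  pvals <- unlist(lapply(1:20, function(i) {
    w <- matrix(rexp(100), 10, 10); diag(w) <- 0
    m <- connectivity_matrix(w, kind = "ppi_z_group")
    randomization_null_weighted(m, n_rand = 400, rng_seed = i)$nodes$p_value
  }))
  # proportion below alpha matches alpha within Monte-Carlo error
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 0.045)
  expect_lt(abs(mean(pvals < 0.3) - 0.3), 0.07)
})
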