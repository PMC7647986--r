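test_that("degree and strength: closed forms and row-sum oracle", {
  empty <- weighted_network(matrix(0, 4, 4))
  expect_equal(net_degree(empty), rep(0L, 4))
  expect_equal(net_strength(empty), rep(0, 4))

  K4 <- weighted_network(matrix(1, 4, 4) - diag(4))
  expect_equal(net_degree(K4), rep(3L, 4))
  expect_equal(net_strength(K4), rep(3, 4))

  one <- matrix(0, 3, 3)
  one[1, 2] <- one[2, 1] <- 5
  expect_equal(net_strength(weighted_network(one)), c(5, 5, 0))

  net <- random_weighted_net(30, 0.2, seed = 4)
  expect_equal(net_degree(net), as.integer(colSums(net$weights > 0)))
  expect_equal(net_strength(net), colSums(net$weights))
})

test_that("betweenness: path graph, star, and brute-force oracle", {
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(net_betweenness(weighted_network(P3)), c(0, 1, 0))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(net_betweenness(weighted_network(star)), c(6, 0, 0, 0, 0))

  for (s in 1:5) {
    net <- random_weighted_net(20, 0.25, seed = s)
    expect_equal(net_betweenness(net), oracle_betweenness(net$weights),
                 tolerance = 1e-9)
  }
  # betweenness is invariant under uniform weight scaling
  net <- random_weighted_net(15, 0.3, seed = 9)
  scaled <- weighted_network(net$weights * 7)
  expect_equal(net_betweenness(scaled), net_betweenness(net),
               tolerance = 1e-9)
})

test_that("local efficiency: conventions and symbol-by-symbol oracle", {
  # isolated node and leaf have efficiency 0
  one <- matrix(0, 3, 3)
  one[1, 2] <- one[2, 1] <- 2
  expect_equal(net_local_efficiency(weighted_network(one)), c(0, 0, 0))

  # triangle with unit weights: e_i = 1
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(net_local_efficiency(weighted_network(tri)), rep(1, 3))

  for (s in 1:4) {
    net <- random_weighted_net(15, 0.35, seed = 10 + s)
    expect_equal(net_local_efficiency(net),
                 oracle_efficiency(net$weights), tolerance = 1e-9)
  }
})

test_that("Onnela clustering: closed forms and triple-product oracle", {
  tri <- matrix(2, 3, 3) - diag(2, 3)
  diag(tri) <- 0
  expect_equal(net_clustering(weighted_network(tri)), rep(1, 3))

  # trees have no triangles
  tree <- matrix(0, 5, 5)
  tree[1, 2] <- tree[1, 3] <- tree[2, 4] <- tree[2, 5] <- 1
  tree <- tree + t(tree)
  expect_equal(net_clustering(weighted_network(tree)), rep(0, 5))

  for (s in 1:4) {
    net <- random_weighted_net(20, 0.3, seed = 20 + s)
    expect_equal(net_clustering(net), oracle_clustering(net$weights),
                 tolerance = 1e-9)
  }
  expect_error(net_clustering(weighted_network(matrix(0, 3, 3))),
               "zero")
})

test_that("modularity partition recovers planted modules", {
  # two 5-cliques joined by one edge -> two modules
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  diag(W) <- 0
  W[5, 6] <- W[6, 5] <- 1
  part <- partition_modules(weighted_network(W), gamma = 1, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_length(unique(part$module_id[1:5]), 1)
  expect_length(unique(part$module_id[6:10]), 1)
  expect_false(part$module_id[1] == part$module_id[10])

  # planted 4-module cohort: adjusted Rand index >= 0.9 vs ground truth
  skip_if_not_installed("mclust")
  su <- gen_network_cohort(cohort_spec(n_subjects = 1, n_patches = 120,
                                       n_h3 = 0, n_h2 = 0,
                                       hub_degree_boost = 0,
                                       hub_crossmodule_prob = 0.05,
                                       n_modules = 4, seed = 8))[[1]]
  part2 <- partition_modules(su$network, gamma = 1, seed = 2)
  ari <- mclust::adjustedRandIndex(part2$module_id, su$module)
  expect_gte(ari, 0.9)

  # deterministic given seed
  part3 <- partition_modules(su$network, gamma = 1, seed = 2)
  expect_identical(part2$module_id, part3$module_id)
  expect_error(partition_modules(weighted_network(matrix(0, 3, 3))),
               "empty")
})

test_that("participation coefficient: closed forms, oracle and bounds", {
  # all edges inside own module -> 0
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  net <- weighted_network(W)
  part <- structure(list(module_id = c(1L, 1L, 2L, 2L), n_modules = 2L,
                         gamma = 1, Q = 0, seed = 1),
                    class = "module_partition")
  expect_equal(net_participation(net, part), rep(0, 4))

  # even split across 2 modules -> 0.5
  Wx <- matrix(0, 3, 3)
  Wx[1, 2] <- Wx[2, 1] <- Wx[1, 3] <- Wx[3, 1] <- 1
  px <- structure(list(module_id = c(1L, 1L, 2L), n_modules = 2L,
                       gamma = 1, Q = 0, seed = 1),
                  class = "module_partition")
  expect_equal(net_participation(weighted_network(Wx), px)[1], 0.5)

  for (s in 1:4) {
    net <- random_weighted_net(25, 0.3, seed = 30 + s)
    memb <- withr::with_seed(s, sample.int(4, 25, replace = TRUE))
    pr <- structure(list(module_id = memb, n_modules = 4L, gamma = 1,
                         Q = 0, seed = 1), class = "module_partition")
    p <- net_participation(net, pr)
    expect_equal(p, oracle_participation(net$weights, memb),
                 tolerance = 1e-12)
    # p in [0, 1 - 1/M]
    expect_true(all(p >= 0 & p <= 1 - 1 / 4 + 1e-12))
  }
})

test_that("compute_all_metrics bundles consistently and deterministically", {
  su <- gen_network_cohort(cohort_spec(n_subjects = 1, n_patches = 60,
                                       n_h3 = 10, n_h2 = 30, seed = 3))[[1]]
  mt <- compute_all_metrics(su$network, gamma = 1, seed = 5, subject_id = 7)
  expect_equal(nrow(mt), 60)
  expect_true(all(mt$degree >= 0 & mt$strength >= 0 & mt$betweenness >= 0))
  expect_true(all(mt$clustering >= 0 & mt$clustering <= 1))
  expect_true(all(mt$participation >= 0 & mt$participation < 1))
  # planted hubs beat ordinary gyral nodes
  expect_gt(mean(mt$degree[mt$class == "H3"]),
            mean(mt$degree[mt$class == "H2"]))
  mt2 <- compute_all_metrics(su$network, gamma = 1, seed = 5, subject_id = 7)
  expect_identical(mt, mt2)

  # metric invariance under node relabeling
  perm <- withr::with_seed(2, sample.int(60))
  net_p <- weighted_network(su$network$weights[perm, perm])
  expect_equal(net_degree(net_p), net_degree(su$network)[perm])
  expect_equal(net_betweenness(net_p), net_betweenness(su$network)[perm],
               tolerance = 1e-9)
  # strength scales linearly under uniform weight scaling
  expect_equal(net_strength(weighted_network(su$network$weights * 3)),
               3 * net_strength(su$network))
})
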