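test_that("gen_folded_surface plants the requested skeleton", {
  # no junctions, one straight ridge -> empty hinge ground truth
  s0 <- gen_folded_surface(n_ridges = 1, n_junctions = 0, seed = 2)
  expect_equal(nrow(s0$ground_truth$hinge_locations), 0)
  expect_gte(s0$ground_truth$basin_count, 1)

  # one Y junction -> exactly one ground-truth hinge at the Y centre,
  # sitting on three skeleton polylines
  s1 <- gen_folded_surface(n_junctions = 1, mesh_resolution = 1, seed = 5)
  gt <- s1$ground_truth
  expect_equal(nrow(gt$hinge_locations), 1)
  touching <- vapply(gt$ridge_skeleton, function(seg) {
    min(sqrt(rowSums((seg[, 1:2] - matrix(gt$hinge_locations[1, 1:2],
                                          nrow(seg), 2,
                                          byrow = TRUE))^2))) < 1e-9
  }, logical(1))
  expect_equal(sum(touching), 3)

  # altitude is positive on the skeleton, negative far from it
  mesh <- s1$mesh
  ctr <- gt$hinge_locations[1, 1:2]
  d_ctr <- sqrt((mesh$vertices[, 1] - ctr[1])^2 +
                  (mesh$vertices[, 2] - ctr[2])^2)
  expect_gt(mesh$altitude[which.min(d_ctr)], 0)
  expect_lt(min(mesh$altitude), 0)
})

test_that("gen_folded_surface is a pure function of its seed", {
  a <- gen_folded_surface(n_junctions = 5, seed = 11)
  b <- gen_folded_surface(n_junctions = 5, seed = 11)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- gen_folded_surface(n_junctions = 5, seed = 12)
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("gen_folded_surface rejects infeasible layouts", {
  expect_error(gen_folded_surface(n_junctions = 1, mesh_resolution = 5),
               "infeasible")
  expect_error(gen_folded_surface(n_junctions = 1, arm_length = 2),
               "infeasible")
  expect_error(gen_folded_surface(n_ridges = 0, n_junctions = 0),
               "at least one")
})

test_that("gen_network_cohort plants exchangeable or boosted hubs", {
  # null spec: H3 and H2 construction identical
  null_spec <- cohort_spec(n_subjects = 3, n_patches = 60, n_h3 = 10,
                           n_h2 = 30, hub_degree_boost = 0,
                           hub_crossmodule_prob = 0.05, p_out = 0.05,
                           seed = 4)
  coh <- gen_network_cohort(null_spec)
  expect_length(coh, 3)
  for (su in coh) {
    W <- su$network$weights
    expect_true(all(W >= 0))
    expect_equal(W, t(W))
    expect_equal(diag(W), rep(0, 60))
    expect_length(su$hub_ids, 10)
  }

  # determinism
  coh2 <- gen_network_cohort(null_spec)
  expect_identical(coh[[1]]$network$weights, coh2[[1]]$network$weights)

  # boosted spec: H3 mean degree exceeds H2 mean degree in every subject
  boosted <- cohort_spec(n_subjects = 5, n_patches = 80, n_h3 = 12,
                         n_h2 = 40, hub_degree_boost = 2, seed = 9)
  for (su in gen_network_cohort(boosted)) {
    deg <- net_degree(su$network)
    expect_gt(mean(deg[su$labels == "H3"]), mean(deg[su$labels == "H2"]))
  }
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_patches = 20, n_h3 = 15, n_h2 = 10), "exceeds")
  expect_error(cohort_spec(hub_crossmodule_prob = 1.2), "0, 1")
  expect_error(cohort_spec(n_patches = 5, n_h3 = 1, n_h2 = 1, n_modules = 9),
               "n_modules")
})

test_that("gen_streamlines inverts the endpoint counting rule", {
  surf <- gen_folded_surface(n_junctions = 1, seed = 3)
  parc <- equal_area_parcellate(surf$mesh, 20, seed = 1)

  # empty set
  empty <- gen_streamlines(surf$mesh, parc, matrix(0, 20, 20), 0, seed = 1)
  expect_equal(empty$total_count, 0)

  # a single heavy pair: all fibers join patches 3 and 7
  M <- matrix(0, 20, 20)
  M[3, 7] <- M[7, 3] <- 500
  sl <- gen_streamlines(surf$mesh, parc, M, 500, seed = 2)
  expect_equal(sl$total_count, 500)
  asg <- attr(sl, "assignments")
  expect_true(all(asg$patch_i == 3 & asg$patch_j == 7))

  # count-sum validation
  expect_error(gen_streamlines(surf$mesh, parc, M, 400, seed = 2),
               "sum to total_fibers")
  Mb <- M
  Mb[3, 7] <- 100
  expect_error(gen_streamlines(surf$mesh, parc, Mb, 500, seed = 2),
               "symmetric")
})

test_that("gen_signal_matrix honours its sparsity ground truth", {
  sig <- gen_signal_matrix(t = 40, n = 50, k = 8, sparsity = 1,
                           noise_sd = 0, seed = 6)
  gt <- sig$ground_truth
  expect_equal(gt$support_counts, rep(1L, 50))
  expect_equal(gt$support_counts,
               as.integer(colSums(gt$true_coefficients != 0)))
  # each noiseless column is an exact scalar multiple of one atom
  for (i in c(1, 25, 50)) {
    j <- which(gt$true_coefficients[, i] != 0)
    expect_equal(sig$X[, i],
                 gt$true_dictionary[, j] * gt$true_coefficients[j, i])
  }
  # k = 400 accepted as component count
  big <- gen_signal_matrix(t = 30, n = 10, k = 400, sparsity = 3, seed = 1)
  expect_equal(dim(big$ground_truth$true_dictionary), c(30, 400))
  # determinism
  sig2 <- gen_signal_matrix(t = 40, n = 50, k = 8, sparsity = 1,
                            noise_sd = 0, seed = 6)
  expect_identical(sig$X, sig2$X)
  expect_error(gen_signal_matrix(t = 40, n = 5, k = 4, sparsity = 9),
               "sparsity")
})
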