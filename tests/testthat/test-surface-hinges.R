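test_that("gyral altitude: flat sheet, mirroring, generator agreement", {
  # a flat plane is its own mid-surface
  pl <- mesh_grid_sheet(15, 15)
  expect_lt(max(abs(compute_gyral_altitude(pl, smoothing_iters = 50))), 1e-6)

  surf <- gen_folded_surface(n_junctions = 5, n_ridges = 1, seed = 3)
  alt <- compute_gyral_altitude(surf$mesh)
  # sign agrees with the planted altitude field on >= 99% of vertices
  expect_gte(mean(sign(alt) == sign(surf$mesh$altitude)), 0.99)
  # roughly centred about the mid-surface
  expect_lt(abs(mean(alt)), 0.05 * sd(alt))

  # flipping face orientation flips the normals, hence the sign
  small <- gen_folded_surface(n_junctions = 1, seed = 2)$mesh
  mirr <- surface_mesh(small$vertices, small$faces[, c(1, 3, 2)])
  a1 <- compute_gyral_altitude(small, 50)
  a2 <- compute_gyral_altitude(mirr, 50)
  expect_equal(a2, -a1)

  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        matrix(1:3, 1))
  expect_error(compute_gyral_altitude(degen), "zero-area")
})

test_that("watershed separates pits and keeps threshold semantics", {
  n <- 41
  xs <- seq(0, 40, length.out = n)
  two_pits <- function(x, y) {
    1 - 3 * exp(-((x - 12)^2 + (y - 20)^2) / 30) -
      3 * exp(-((x - 28)^2 + (y - 20)^2) / 30)
  }
  h <- as.vector(outer(xs, xs, two_pits))
  mesh <- mesh_grid_sheet(n, n, 1, height = h)
  seg <- watershed_segment(mesh, level = 0)
  expect_equal(seg$n_basins, 2L)
  # the two pit centres fall into different basins, separated by the
  # crest along the analytic ridge line x = 20
  vid <- function(x, y) (y) * n + x + 1   # 0-based grid coords
  expect_true(seg$basin_id[vid(12, 20)] > 0)
  expect_true(seg$basin_id[vid(28, 20)] > 0)
  expect_false(seg$basin_id[vid(12, 20)] == seg$basin_id[vid(28, 20)])
  expect_true(seg$crest_mask[vid(20, 20)])

  # single pit: one basin and no collision ridge
  one_pit <- function(x, y) 1 - 3 * exp(-((x - 20)^2 + (y - 20)^2) / 60)
  mesh1 <- mesh_grid_sheet(n, n, 1, height = as.vector(outer(xs, xs, one_pit)))
  seg1 <- watershed_segment(mesh1, level = 0)
  expect_equal(seg1$n_basins, 1L)
  expect_equal(seg1$crest_mask, mesh1$altitude >= 0)

  # the crest mask shrinks (set inclusion) and basins never vanish as
  # the level rises
  seg_lo <- watershed_segment(mesh, level = -0.5)
  seg_hi <- watershed_segment(mesh, level = 0.5)
  expect_true(all(seg_lo$crest_mask[seg_hi$crest_mask]))
  expect_lte(seg_lo$n_basins, seg_hi$n_basins)

  # basins partition the below-level non-crest vertices connectedly
  g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
  for (b in seq_len(seg$n_basins)) {
    vs <- which(seg$basin_id == b)
    expect_equal(igraph::components(igraph::induced_subgraph(g, vs))$no, 1)
  }
  expect_true(all(seg$basin_id[!seg$crest_mask] > 0))

  expect_error(watershed_segment(mesh, altitude = rep(1, n * n)),
               "constant")
  expect_error(watershed_segment(mesh, level = min(mesh$altitude) - 1),
               "no basins")
})

test_that("collision ridges form between deep basins; shallow pockets merge", {
  # channel profile (y-independent): a deep trough, a saddle at -0.3
  # (x = 15), then a second minimum whose depth is set by `pocket`
  channel_mesh <- function(pocket) {
    n <- 41
    xs <- seq(0, 40, length.out = n)
    prof <- stats::approx(c(0, 4, 5, 10, 15, 20, 25, 40),
                          c(1, 0, -2, -2, -0.3, pocket, 0, 1),
                          xout = xs)$y
    mesh_grid_sheet(n, n, 1, height = rep(prof, times = n))
  }

  # pocket 0.2 mm below the saddle: merged under the default threshold,
  # kept as its own basin when merging is disabled
  shallow <- channel_mesh(-0.5)
  expect_equal(watershed_segment(shallow, level = 0)$n_basins, 1L)
  seg0 <- watershed_segment(shallow, level = 0, min_basin_depth = 0)
  expect_equal(seg0$n_basins, 2L)

  # pocket 1.2 mm below the saddle: a genuine basin; the collision
  # ridge sits within one edge of the analytic saddle x = 15
  deep <- channel_mesh(-1.5)
  segd <- watershed_segment(deep, level = 0)
  expect_equal(segd$n_basins, 2L)
  ridge <- which(segd$crest_mask & deep$altitude < 0)
  expect_gt(length(ridge), 0)
  expect_true(all(abs(deep$vertices[ridge, 1] - 15) <= 1))
})

test_that("crest distance transform matches Dijkstra on a strip", {
  mesh <- strip_mesh(nx = 20, width = 5, pad = 2)
  seg <- watershed_segment(mesh, level = 0)
  d <- distance_transform_crest(mesh, seg)
  crest <- which(seg$crest_mask)

  # independent O(n^2) Dijkstra from the border vertices
  e <- mesh_edges(mesh)
  keep <- seg$crest_mask[e[, 1]] & seg$crest_mask[e[, 2]]
  ec <- e[keep, , drop = FALSE]
  len <- mesh_edge_lengths(mesh, ec)
  adj <- vector("list", nrow(mesh$vertices))
  basin <- seg$basin_id > 0
  border <- crest[vapply(crest, function(v) {
    nb <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
    any(basin[nb])
  }, logical(1))]
  ref <- oracle_multisource_dijkstra(nrow(mesh$vertices), ec, len, border)
  expect_equal(d[crest], ref[crest], tolerance = 1e-12)

  # strip of width 5 rows: border rows at 0, centreline at 2
  expect_equal(min(d[crest]), 0)
  expect_equal(max(d[crest]), 2)
  # 1-Lipschitz along crest edges
  expect_true(all(abs(d[ec[, 1]] - d[ec[, 2]]) <= len + 1e-9))
})

test_that("tree marching roots at crest centres and spans the crest", {
  mesh <- strip_mesh(nx = 21, width = 5, pad = 2)
  seg <- watershed_segment(mesh, level = 0)
  d <- distance_transform_crest(mesh, seg)
  forest <- build_crest_trees(mesh, seg, d)
  crest <- which(seg$crest_mask)

  # partition: every crest vertex has a parent pointer or is a root
  expect_true(all(!is.na(forest$parent[crest])))
  expect_true(all(is.na(forest$parent[-crest])))
  roots <- crest[forest$parent[crest] == 0]
  expect_length(roots, 1)           # one connected crest component
  expect_equal(d[roots], max(d[crest]))

  # distances never increase from parent to child
  kids <- crest[forest$parent[crest] > 0]
  expect_true(all(d[forest$parent[kids]] >= d[kids] - 1e-9))

  # a single-vertex crest component is its own root
  v <- diag(3)
  tiny <- surface_mesh(rbind(c(0, 0, 1), c(1, 0, -1), c(0, 1, -1)),
                       matrix(1:3, 1), altitude = c(1, -1, -1))
  seg_t <- watershed_segment(tiny, level = 0)
  d_t <- distance_transform_crest(tiny, seg_t)
  f_t <- build_crest_trees(tiny, seg_t, d_t)
  expect_equal(f_t$parent[1], 0L)
})

test_that("pruning removes short branches to a fixpoint", {
  # hand-built forest: Y with three 8 mm arms -> one 3-hinge
  mk_y <- function(short_arm = FALSE) {
    pts <- rbind(c(0, 0, 0))
    parent <- c(0L)
    for (arm in 0:2) {
      ang <- arm * 2 * pi / 3
      len <- if (short_arm && arm == 2) 3 else 8
      prev <- 1L
      for (r in seq_len(len)) {
        pts <- rbind(pts, c(r * cos(ang), r * sin(ang), 0))
        parent <- c(parent, prev)
        prev <- nrow(pts)
      }
    }
    mesh <- surface_mesh(pts, matrix(integer(0), 0, 3))
    forest <- structure(list(parent = parent, crest = seq_len(nrow(pts)),
                             distance = rep(1, nrow(pts))),
                        class = "crest_forest")
    list(mesh = mesh, forest = forest)
  }

  y <- mk_y()
  cg <- prune_and_extract(y$forest, y$mesh, length_threshold = 6)
  expect_equal(nrow(cg$hinges), 1)
  expect_equal(cg$hinges$arm_count, 3L)
  expect_equal(cg$hinges$vertex, 1L)
  expect_length(cg$nodes, 25)       # nothing pruned

  # one short arm (3 mm < 6 mm): pruned away, no hinge remains
  ys <- mk_y(short_arm = TRUE)
  cgs <- prune_and_extract(ys$forest, ys$mesh, length_threshold = 6)
  expect_equal(nrow(cgs$hinges), 0)
  expect_length(cgs$nodes, 17)      # two 8 mm arms + centre survive

  # straight trunk: unchanged, no hinges
  pts <- cbind(0:10, 0, 0)
  trunk <- structure(list(parent = c(0L, 1:10), crest = 1:11,
                          distance = rep(1, 11)), class = "crest_forest")
  tm <- surface_mesh(pts, matrix(integer(0), 0, 3))
  cgt <- prune_and_extract(trunk, tm, length_threshold = 6)
  expect_length(cgt$nodes, 11)
  expect_equal(nrow(cgt$hinges), 0)

  # idempotence: pruning the pruned graph changes nothing
  reforest <- function(cg, n_total) {
    parent <- rep(NA_integer_, n_total)
    parent[cg$nodes] <- 0L
    if (nrow(cg$edges) > 0) {
      g <- igraph::graph_from_edgelist(cg$edges, directed = FALSE)
      bfs <- igraph::bfs(g, root = cg$nodes[1], unreachable = FALSE,
                         father = TRUE)
      fa <- as.integer(bfs$father)
      for (v in cg$nodes) {
        if (!is.na(fa[v]) && fa[v] > 0) parent[v] <- fa[v]
      }
    }
    structure(list(parent = parent, crest = cg$nodes,
                   distance = rep(1, n_total)), class = "crest_forest")
  }
  f2 <- reforest(cgs, nrow(ys$mesh$vertices))
  cg2 <- prune_and_extract(f2, ys$mesh, length_threshold = 6)
  expect_setequal(cg2$nodes, cgs$nodes)
  expect_equal(nrow(cg2$hinges), nrow(cgs$hinges))
})

test_that("detect_hinges recovers planted junctions", {
  # one planted Y junction -> exactly one 3-hinge within 2 mm
  surf <- gen_folded_surface(n_junctions = 1, mesh_resolution = 1, seed = 7)
  cg <- detect_hinges(surf$mesh)
  st <- hinge_match_stats(cg, surf$ground_truth)
  expect_equal(unname(st["n_det"]), 1)
  expect_equal(unname(st["hit"]), 1)

  # no junctions -> no hinges
  s0 <- gen_folded_surface(n_ridges = 1, n_junctions = 0, seed = 2)
  expect_equal(nrow(detect_hinges(s0$mesh)$hinges), 0)

  # relabeling the vertices permutes the census consistently
  mesh <- surf$mesh
  nv <- nrow(mesh$vertices)
  perm <- withr::with_seed(1, sample.int(nv))
  inv <- integer(nv)
  inv[perm] <- seq_len(nv)
  mesh_p <- surface_mesh(mesh$vertices[perm, ],
                         matrix(inv[mesh$faces], ncol = 3),
                         altitude = mesh$altitude[perm])
  cg_p <- detect_hinges(mesh_p)
  expect_equal(nrow(cg_p$hinges), nrow(cg$hinges))
  expect_equal(sort(cg_p$hinges$arm_count), sort(cg$hinges$arm_count))
  # hinge locations agree to within one edge (index tie-breaks may move
  # a hinge to an adjacent vertex)
  d <- sqrt((cg_p$hinges$x - cg$hinges$x)^2 + (cg_p$hinges$y - cg$hinges$y)^2)
  expect_true(all(d <= sqrt(2)))
})
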