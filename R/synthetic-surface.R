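#' Generate a folded sheet with a planted gyral crest skeleton
#'
#' Builds a rectangular triangulated sheet whose altitude field is a sum of
#' Gaussian ridge bumps along a planted crest skeleton: `n_junctions`
#' Y-shaped three-way ridge junctions plus `n_ridges` standalone straight
#' ridges. The altitude is recentred to zero mean so that ridges are
#' positive and basins negative about the mid-surface, and the sheet is
#' embedded with z = altitude. The returned ground truth records the
#' junction centres and skeleton polylines, giving an analytic reference
#' for crest-line and hinge detection.
#'
#' Features are laid out on a jittered grid of cells sized from
#' `arm_length`, so junctions can never collide; infeasible parameter
#' combinations (a mesh too coarse to resolve the ridge profile, or arms
#' too short to survive crest-line pruning) raise an error rather than
#' silently overlapping features.
#'
#' @param n_ridges Number of standalone straight ridges (>= 0).
#' @param n_junctions Number of planted Y junctions (>= 0).
#' @param mesh_resolution Grid edge length (mm).
#' @param seed Integer seed; the generator is a pure function of it.
#' @param arm_length Length of each junction arm (mm).
#' @param ridge_sigma Gaussian ridge half-width parameter (mm).
#' @param ridge_height Ridge bump amplitude (mm).
#' @return A list with components `mesh` (a [surface_mesh] whose altitude
#'   is the planted field) and `ground_truth` (list: `hinge_locations`
#'   matrix of junction centres, `ridge_skeleton` list of polylines,
#'   `basin_count`).
#' @export
gen_folded_surface <- function(n_ridges = 0, n_junctions = 1,
                               mesh_resolution = 1, seed = 1,
                               arm_length = 10, ridge_sigma = 1.5,
                               ridge_height = 4) {
  stopifnot(n_ridges >= 0, n_junctions >= 0, mesh_resolution > 0)
  nf <- n_ridges + n_junctions
  if (nf < 1) stop_hinge("at least one ridge or junction is required")
  if (mesh_resolution > ridge_sigma) {
    stop_hinge("infeasible skeleton layout: mesh_resolution exceeds ",
               "ridge_sigma, ridges cannot be resolved")
  }
  if (arm_length < 4 * ridge_sigma) {
    stop_hinge("infeasible skeleton layout: arms shorter than 4 * ridge_sigma ",
               "would merge with the junction core")
  }

  n_cells <- ceiling(sqrt(nf))
  cell <- 2 * arm_length + 8
  margin <- 4
  extent <- n_cells * cell + 2 * margin

  with_seed(seed, {
    # feature centres: jittered cell centres, shuffled cell order
    cells <- utils::head(sample(n_cells^2), nf)
    ci <- (cells - 1) %% n_cells
    cj <- (cells - 1) %/% n_cells
    cx <- margin + ci * cell + cell / 2 + runif(nf, -2, 2)
    cy <- margin + cj * cell + cell / 2 + runif(nf, -2, 2)

    segs <- list()
    hinge_xy <- matrix(numeric(0), 0, 2)
    skeleton <- list()
    for (q in seq_len(nf)) {
      ctr <- c(cx[q], cy[q])
      if (q <= n_junctions) {
        base <- runif(1, 0, 2 * pi / 3)
        for (ang in base + c(0, 2 * pi / 3, 4 * pi / 3)) {
          tip <- ctr + arm_length * c(cos(ang), sin(ang))
          segs[[length(segs) + 1L]] <- rbind(ctr, tip)
          skeleton[[length(skeleton) + 1L]] <- rbind(ctr, tip)
        }
        hinge_xy <- rbind(hinge_xy, ctr)
      } else {
        ang <- runif(1, 0, pi)
        dirv <- c(cos(ang), sin(ang))
        a <- ctr - arm_length * dirv
        b <- ctr + arm_length * dirv
        segs[[length(segs) + 1L]] <- rbind(a, b)
        skeleton[[length(skeleton) + 1L]] <- rbind(a, b)
      }
    }

    nx <- floor(extent / mesh_resolution) + 1L
    sheet <- mesh_grid_sheet(nx, nx, spacing = mesh_resolution)
    xy <- sheet$vertices[, 1:2]

    d <- rep(Inf, nrow(xy))
    for (s in segs) {
      d <- pmin(d, point_segment_distance(xy, s[1, ], s[2, ]))
    }
    bump <- ridge_height * exp(-d^2 / (2 * ridge_sigma^2))
    altitude <- bump - mean(bump)

    verts <- cbind(xy, altitude)
    mesh <- surface_mesh(verts, sheet$faces, altitude = altitude)

    # ground-truth hinge locations in 3-D (z = altitude at the centre)
    hinge_loc <- matrix(numeric(0), 0, 3)
    if (nrow(hinge_xy) > 0) {
      hz <- ridge_height * exp(0) - mean(bump)
      hinge_loc <- cbind(hinge_xy, rep(hz, nrow(hinge_xy)))
      colnames(hinge_loc) <- c("x", "y", "z")
    }

    basin_count <- count_components(mesh, altitude < 0)

    list(
      mesh = mesh,
      ground_truth = list(
        hinge_locations = hinge_loc,
        ridge_skeleton = skeleton,
        basin_count = basin_count
      )
    )
  })
}

# distance from each row of `p` (n x 2) to segment a-b
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap1 <- p[, 1] - a[1]
  ap2 <- p[, 2] - a[2]
  t <- if (len2 == 0) rep(0, nrow(p)) else (ap1 * ab[1] + ap2 * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- ap1 - t * ab[1]
  dy <- ap2 - t * ab[2]
  sqrt(dx^2 + dy^2)
}

count_components <- function(mesh, mask) {
  ids <- which(mask)
  if (length(ids) == 0L) return(0L)
  g <- mesh_graph(mesh)
  sub <- igraph::induced_subgraph(g, ids)
  igraph::components(sub)$no
}
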