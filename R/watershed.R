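#' Watershed segmentation of gyral crests from sulcal basins
#'
#' Vertices below the altitude `level` are flooded in ascending altitude
#' order: each one joins the basin of its already-flooded neighbours,
#' starts a new basin when it is a fresh local minimum, or — when two
#' distinct basins meet at it — either merges them or becomes a
#' collision-ridge vertex. A basin whose depth below the meeting saddle
#' is less than `min_basin_depth` is merged into its deeper neighbour
#' (shallow spurious minima do not deserve a separating ridge); when two
#' basins deeper than that meet, the meeting vertex joins the crest.
#' Vertices at or above `level` plus these collision ridges form the
#' gyral crest mask separating the sulcal basins. Plateaus are resolved
#' by the deterministic ascending (altitude, vertex index) processing
#' order.
#'
#' @param mesh A [surface_mesh].
#' @param altitude Per-vertex altitude (mm); defaults to `mesh$altitude`.
#' @param level Crest threshold (mm). Default 0, the mid-surface.
#' @param min_basin_depth Persistence threshold (mm): basins shallower
#'   than this at their first collision are merged away. Real sulcal
#'   basins are many mm deep, so the default only suppresses numerical
#'   pocket minima.
#' @return An object of class `basin_segmentation`: list with `basin_id`
#'   (per-vertex integer, -1 on the crest, contiguous 1..n_basins),
#'   `crest_mask` (logical), `n_basins`, and `level`.
#' @export
watershed_segment <- function(mesh, altitude = mesh$altitude, level = 0,
                              min_basin_depth = 0.5) {
  if (is.null(altitude)) stop_hinge("no altitude field available")
  altitude <- as.numeric(altitude)
  nv <- n_vertices(mesh)
  if (length(altitude) != nv) stop_hinge("altitude length must match vertex count")
  if (diff(range(altitude)) == 0) stop_hinge("constant altitude field: no basins")
  below <- which(altitude < level)
  if (length(below) == 0L) stop_hinge("no vertices below level: no basins")

  adj <- mesh_adjacency(mesh)
  basin <- integer(nv)          # 0 = unassigned, -1 = crest, k > 0 = basin k
  basin[altitude >= level] <- -1L
  ord <- below[order(altitude[below], below)]

  parent <- integer(0)          # union-find over basin ids
  min_alt <- numeric(0)
  find <- function(b) {
    while (parent[b] != b) b <- parent[b]
    b
  }
  for (v in ord) {
    labs <- basin[adj[[v]]]
    labs <- labs[labs > 0L]
    roots <- unique(vapply(labs, find, integer(1)))
    if (length(roots) == 0L) {
      nb <- length(parent) + 1L
      parent[nb] <- nb
      min_alt[nb] <- altitude[v]
      basin[v] <- nb
    } else if (length(roots) == 1L) {
      basin[v] <- roots
    } else {
      h <- altitude[v]
      deep <- roots[h - min_alt[roots] >= min_basin_depth]
      keep <- roots[which.min(min_alt[roots])]
      if (length(deep) >= 2L) {
        # genuine watershed line: merge only the shallow participants
        shallow <- setdiff(roots, deep)
        into <- deep[which.min(min_alt[deep])]
        for (b in shallow) parent[b] <- into
        basin[v] <- -1L
      } else {
        for (b in setdiff(roots, keep)) parent[b] <- keep
        basin[v] <- keep
      }
    }
  }
  # resolve unions and relabel contiguously
  pos <- basin > 0L
  if (any(pos)) {
    roots <- vapply(basin[pos], find, integer(1))
    uniq <- sort(unique(roots))
    basin[pos] <- match(roots, uniq)
    n_basins <- length(uniq)
  } else {
    n_basins <- 0L
  }
  structure(
    list(basin_id = basin, crest_mask = basin == -1L,
         n_basins = n_basins, level = level),
    class = "basin_segmentation"
  )
}

#' @export
print.basin_segmentation <- function(x, ...) {
  cat(sprintf("<basin_segmentation> %d basins, %d crest vertices (level %g mm)\n",
              x$n_basins, sum(x$crest_mask), x$level))
  invisible(x)
}
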