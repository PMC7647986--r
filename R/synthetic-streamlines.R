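#' Streamline set
#'
#' A list of 3-D polylines (matrices in mm, one row per point, >= 2 rows).
#'
#' @param polylines List of numeric matrices with 3 columns.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(polylines) {
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 3L || nrow(p) < 2L) {
      stop_hinge("each polyline needs >= 2 points with 3 coordinates")
    }
    p
  })
  structure(list(polylines = polylines, total_count = length(polylines)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines\n", x$total_count))
  invisible(x)
}

#' Generate streamlines realising a requested patch-pair count matrix
#'
#' Inverts the connectome counting rule: for every unordered patch pair
#' (i, j) with a positive entry in `target_counts`, that many polylines
#' are created whose endpoints sit exactly on randomly chosen vertices of
#' patches i and j (so endpoint snapping recovers the assignment, and
#' recounting endpoint pairs reproduces `target_counts` exactly). The
#' interior of each polyline is an arched midpoint, irrelevant to
#' endpoint-based counting.
#'
#' @param mesh A [surface_mesh].
#' @param parc A `parcellation` of the mesh.
#' @param target_counts Symmetric nonnegative integer matrix
#'   (n_patches x n_patches); its upper triangle (including the diagonal
#'   for within-patch fibers) sums to `total_fibers`.
#' @param total_fibers Total number of fibers (checked against
#'   `target_counts`).
#' @param seed Integer seed.
#' @return A `streamline_set` with an `assignments` attribute (tibble:
#'   `fiber`, `patch_i`, `patch_j`).
#' @export
gen_streamlines <- function(mesh, parc, target_counts, total_fibers, seed = 1) {
  target_counts <- as.matrix(target_counts)
  np <- parc$n_patches
  if (nrow(target_counts) != np || ncol(target_counts) != np) {
    stop_hinge("target_counts must be n_patches x n_patches")
  }
  if (max(abs(target_counts - t(target_counts))) > 0) {
    stop_hinge("target_counts must be symmetric")
  }
  if (any(target_counts < 0)) stop_hinge("target_counts must be nonnegative")
  ut_sum <- sum(target_counts[upper.tri(target_counts, diag = TRUE)])
  if (ut_sum != total_fibers) {
    stop_hinge("target_counts upper triangle must sum to total_fibers")
  }
  patch_verts <- split(seq_along(parc$patch_id), parc$patch_id)
  if (length(patch_verts) < np || any(lengths(patch_verts) == 0L)) {
    stop_hinge("every patch must contain at least one vertex")
  }
  if (total_fibers == 0) {
    out <- streamline_set(list())
    attr(out, "assignments") <- tibble(fiber = integer(0),
                                       patch_i = integer(0),
                                       patch_j = integer(0))
    return(out)
  }

  idx <- which(upper.tri(target_counts, diag = TRUE) & target_counts > 0,
               arr.ind = TRUE)
  pi_all <- rep(idx[, 1], target_counts[idx])
  pj_all <- rep(idx[, 2], target_counts[idx])
  v <- mesh$vertices
  polys <- with_seed(seed, {
    lapply(seq_along(pi_all), function(f) {
      a <- v[patch_verts[[pi_all[f]]][sample.int(length(patch_verts[[pi_all[f]]]), 1)], ]
      b <- v[patch_verts[[pj_all[f]]][sample.int(length(patch_verts[[pj_all[f]]]), 1)], ]
      mid <- (a + b) / 2
      mid[3] <- mid[3] - max(1, sqrt(sum((a - b)^2)) / 4)  # dive below surface
      rbind(a, mid, b)
    })
  })
  out <- streamline_set(polys)
  attr(out, "assignments") <- tibble(fiber = seq_along(pi_all),
                                     patch_i = as.integer(pi_all),
                                     patch_j = as.integer(pj_all))
  out
}
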