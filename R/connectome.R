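#' Map streamline endpoints to cortical patches
#'
#' Each streamline endpoint snaps to the patch of its nearest mesh vertex
#' when that vertex lies within `snap_mm`; otherwise the endpoint is
#' non-cortical (`NA`). Pairs are order-normalised (`patch_i <= patch_j`,
#' `NA` sorted last).
#'
#' @param streamlines A `streamline_set`.
#' @param mesh A [surface_mesh].
#' @param parc A `parcellation` of the mesh.
#' @param snap_mm Endpoint snap distance (mm), > 0. Default 2.
#' @return Tibble with one row per fiber: `fiber`, `patch_i`, `patch_j`
#'   (integer patch ids, `NA` = non-cortical).
#' @export
assign_endpoints <- function(streamlines, mesh, parc, snap_mm = 2) {
  stopifnot(snap_mm > 0)
  nf <- streamlines$total_count
  if (nf == 0L) {
    return(tibble(fiber = integer(0), patch_i = integer(0),
                  patch_j = integer(0)))
  }
  ends1 <- t(vapply(streamlines$polylines, function(p) p[1, ], numeric(3)))
  ends2 <- t(vapply(streamlines$polylines, function(p) p[nrow(p), ], numeric(3)))
  p1 <- snap_points_to_patches(ends1, mesh, parc, snap_mm)
  p2 <- snap_points_to_patches(ends2, mesh, parc, snap_mm)
  lo <- pmin(p1, p2, na.rm = FALSE)
  hi <- pmax(p1, p2, na.rm = FALSE)
  # NA-aware normalisation: put the non-NA patch first
  swap <- is.na(p1) & !is.na(p2)
  pi_ <- ifelse(is.na(p1) | is.na(p2), ifelse(swap, p2, p1), lo)
  pj_ <- ifelse(is.na(p1) | is.na(p2), ifelse(swap, p1, p2), hi)
  tibble(fiber = seq_len(nf), patch_i = as.integer(pi_),
         patch_j = as.integer(pj_))
}

# nearest-vertex snap, chunked so the distance matrix stays small
snap_points_to_patches <- function(pts, mesh, parc, snap_mm) {
  v <- mesh$vertices
  vv <- rowSums(v^2)
  out <- integer(nrow(pts))
  chunk <- max(1L, floor(2e6 / nrow(v)))
  for (st in seq(1L, nrow(pts), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(pts))
    P <- pts[st:en, , drop = FALSE]
    d2 <- outer(rowSums(P^2), vv, "+") - 2 * P %*% t(v)
    nearest <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(P)), nearest)]))
    res <- parc$patch_id[nearest]
    res[dmin > snap_mm] <- NA_integer_
    out[st:en] <- res
  }
  out
}

#' Build the weighted connectivity matrix from endpoint pairs
#'
#' The weight between two patches is the number of streamlines with one
#' endpoint in each. Within-patch fibers and fibers with a non-cortical
#' endpoint are excluded from the matrix but retained in the exclusion
#' counts, so cortical + excluded always equals the total fiber count.
#' Weights need no cross-subject normalisation when the total fiber
#' number per subject is fixed.
#'
#' @param pairs Tibble from [assign_endpoints()] (columns `patch_i`,
#'   `patch_j`).
#' @param n_patches Number of patches.
#' @param labels Optional patch labels to attach to the network.
#' @return A [weighted_network]; attribute `excluded` is a list with
#'   `within_patch` and `noncortical` counts.
#' @export
build_connectivity <- function(pairs, n_patches, labels = NULL) {
  pi_ <- pairs$patch_i
  pj_ <- pairs$patch_j
  ok <- !is.na(pi_) & !is.na(pj_)
  if (any(c(pi_[!is.na(pi_)], pj_[!is.na(pj_)]) > n_patches) ||
      any(c(pi_[!is.na(pi_)], pj_[!is.na(pj_)]) < 1L)) {
    stop_hinge("patch index out of range")
  }
  within <- ok & pi_ == pj_
  noncort <- !ok
  keep <- ok & !within
  W <- matrix(0, n_patches, n_patches)
  if (any(keep)) {
    key <- pair_key(pi_[keep], pj_[keep], n_patches)
    cnt <- table(key)
    k <- as.numeric(names(cnt))
    lo <- ((k - 1) %/% n_patches) + 1
    hi <- k - (lo - 1) * n_patches
    W[cbind(lo, hi)] <- as.numeric(cnt)
    W[cbind(hi, lo)] <- as.numeric(cnt)
  }
  net <- weighted_network(W, labels = labels)
  attr(net, "excluded") <- list(within_patch = sum(within),
                                noncortical = sum(noncort))
  net
}

#' Fiber termination density per vertex (fibers / mm^2)
#'
#' Counts the streamline endpoints snapping to each vertex (within
#' `snap_mm`) and divides by the vertex area.
#'
#' @param streamlines A `streamline_set`.
#' @param mesh A [surface_mesh].
#' @param snap_mm Endpoint snap distance (mm).
#' @return Numeric per-vertex density vector.
#' @export
termination_density <- function(streamlines, mesh, snap_mm = 2) {
  va <- mesh_vertex_areas(mesh)
  if (any(va <= 0)) stop_hinge("zero-area vertex: density undefined")
  counts <- numeric(n_vertices(mesh))
  if (streamlines$total_count > 0L) {
    ends <- rbind(
      t(vapply(streamlines$polylines, function(p) p[1, ], numeric(3))),
      t(vapply(streamlines$polylines, function(p) p[nrow(p), ], numeric(3)))
    )
    v <- mesh$vertices
    vv <- rowSums(v^2)
    chunk <- max(1L, floor(2e6 / nrow(v)))
    for (st in seq(1L, nrow(ends), by = chunk)) {
      en <- min(st + chunk - 1L, nrow(ends))
      P <- ends[st:en, , drop = FALSE]
      d2 <- outer(rowSums(P^2), vv, "+") - 2 * P %*% t(v)
      nearest <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(P)), nearest)]))
      hit <- nearest[dmin <= snap_mm]
      if (length(hit)) {
        tb <- tabulate(hit, nbins = n_vertices(mesh))
        counts <- counts + tb
      }
    }
  }
  counts / va
}

#' Area-corrected class connection counts
#'
#' Counts the fibers joining each pair of convolution classes
#' (H3 / H2 / NON) and divides by the summed area of all patches of the
#' two classes, in cm^2 by default. By default NON collects both
#' non-cortical endpoints and sulcal patches; with
#' `non_mode = "noncortical_only"` sulcal-touching fibers are dropped and
#' NON means non-cortical terminations only.
#'
#' @param pairs Tibble from [assign_endpoints()].
#' @param labels Patch label tibble from [label_patches()].
#' @param non_mode `"noncortical_or_sulcal"` (default) or
#'   `"noncortical_only"`.
#' @param area_scale Divisor from mm^2 to the correction unit
#'   (default 100 = cm^2).
#' @return 3x3 symmetric matrix over H3/H2/NON of area-corrected counts;
#'   attributes `raw` (uncorrected counts) and `class_area` (summed areas
#'   in correction units).
#' @export
class_connection_counts <- function(pairs, labels,
                                    non_mode = c("noncortical_or_sulcal",
                                                 "noncortical_only"),
                                    area_scale = 100) {
  non_mode <- match.arg(non_mode)
  cls_of <- function(p) {
    out <- rep("NON", length(p))
    cortical <- !is.na(p)
    pc <- as.character(labels$class[p[cortical]])
    out[cortical] <- ifelse(pc == "SULCAL", "SULCAL", pc)
    out
  }
  c1 <- cls_of(pairs$patch_i)
  c2 <- cls_of(pairs$patch_j)
  if (non_mode == "noncortical_or_sulcal") {
    c1[c1 == "SULCAL"] <- "NON"
    c2[c2 == "SULCAL"] <- "NON"
  } else {
    drop <- c1 == "SULCAL" | c2 == "SULCAL"
    c1 <- c1[!drop]
    c2 <- c2[!drop]
  }
  lev <- c("H3", "H2", "NON")
  raw <- matrix(0, 3, 3, dimnames = list(lev, lev))
  if (length(c1)) {
    tb <- table(factor(pmin(c1, c2), levels = sort(lev)),
                factor(pmax(c1, c2), levels = sort(lev)))
    for (a in lev) for (b in lev) {
      lo <- min(a, b); hi <- max(a, b)
      raw[a, b] <- tb[lo, hi]
    }
  }
  area_cls <- c(
    H3 = sum(labels$area_mm2[labels$class == "H3"]),
    H2 = sum(labels$area_mm2[labels$class == "H2"]),
    NON = if (non_mode == "noncortical_or_sulcal") {
      sum(labels$area_mm2[labels$class == "SULCAL"])
    } else 0
  ) / area_scale
  denom <- outer(area_cls, area_cls, "+")
  diag(denom) <- area_cls  # classes A and B coincide: count the area once
  corrected <- raw / denom
  corrected[!is.finite(corrected)] <- NA_real_
  attr(corrected, "raw") <- raw
  attr(corrected, "class_area") <- area_cls
  corrected
}
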