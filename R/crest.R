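#' Geodesic distance transform of the gyral crest
#'
#' For every crest vertex, the shortest-path (Dijkstra, Euclidean edge
#' lengths) distance to the crest border, i.e. to the nearest crest vertex
#' adjacent to a sulcal basin. Border vertices get distance 0; interior
#' crest centres get the largest values.
#'
#' @param mesh A [surface_mesh].
#' @param seg A `basin_segmentation` from [watershed_segment()].
#' @return Numeric vector over all vertices: distance in mm on the crest,
#'   `NA` elsewhere.
#' @export
distance_transform_crest <- function(mesh, seg) {
  crest <- which(seg$crest_mask)
  if (length(crest) == 0L) stop_hinge("empty crest mask")
  adj <- mesh_adjacency(mesh)
  in_basin <- seg$basin_id > 0L
  border <- crest[vapply(adj[crest],
                         function(nb) any(in_basin[nb]), logical(1))]
  if (length(border) == 0L) {
    stop_hinge("crest has no border with any basin (whole surface is crest)")
  }

  g <- mesh_graph(mesh)
  sub <- igraph::induced_subgraph(g, crest)
  # single virtual source wired to every border vertex with length 0
  loc_border <- match(border, crest)
  src <- igraph::add_vertices(sub, 1)
  src_id <- igraph::vcount(src)
  src <- igraph::add_edges(src,
                           as.vector(rbind(src_id, loc_border)),
                           weight = 0)
  dvec <- as.vector(igraph::distances(src, v = src_id,
                                      algorithm = "dijkstra"))[-src_id]
  if (any(!is.finite(dvec))) {
    stop_hinge("crest component with no border: distance transform undefined")
  }
  out <- rep(NA_real_, n_vertices(mesh))
  out[crest] <- dvec
  out
}

#' Tree marching over the crest distance map
#'
#' Builds one spanning tree per connected crest component. The root is the
#' component's maximum-distance vertex (crest centre); the tree grows
#' outwards by repeatedly attaching the highest-distance frontier vertex
#' to its highest-distance in-tree neighbour, so branches follow the
#' descending distance gradient down to the crest borders. Ties are broken
#' by lowest vertex index.
#'
#' @param mesh A [surface_mesh].
#' @param seg A `basin_segmentation`.
#' @param distance Per-vertex crest distance from
#'   [distance_transform_crest()].
#' @return An object of class `crest_forest`: list with `parent`
#'   (per-vertex integer; 0 marks a root, `NA` off-crest), `crest`
#'   (vertex ids), `distance`.
#' @export
build_crest_trees <- function(mesh, seg, distance) {
  crest <- which(seg$crest_mask)
  if (length(crest) == 0L) stop_hinge("empty crest mask")
  dloc <- distance[crest]
  if (any(is.na(dloc))) stop_hinge("distance not defined on all crest vertices")
  nloc <- length(crest)
  pos <- integer(n_vertices(mesh))
  pos[crest] <- seq_len(nloc)
  adj <- mesh_adjacency(mesh)
  adj_loc <- lapply(adj[crest], function(nb) pos[nb[seg$crest_mask[nb]]])

  g <- mesh_graph(mesh)
  comp <- igraph::components(igraph::induced_subgraph(g, crest))$membership

  parent <- rep(NA_integer_, n_vertices(mesh))
  in_tree <- logical(nloc)
  # frontier score: distance if adjacent to the growing tree, else -Inf
  score <- rep(-Inf, nloc)

  for (cid in seq_len(max(comp))) {
    members <- which(comp == cid)
    root <- members[order(-dloc[members], members)][1]
    parent[crest[root]] <- 0L
    in_tree[root] <- TRUE
    score[adj_loc[[root]]] <- dloc[adj_loc[[root]]]
    score[in_tree] <- -Inf
    for (k in seq_len(length(members) - 1L)) {
      j <- which.max(score)           # ties -> lowest local index
      if (!is.finite(score[j])) break
      nb <- adj_loc[[j]]
      nb <- nb[in_tree[nb]]
      p <- nb[order(-dloc[nb], nb)][1]
      parent[crest[j]] <- crest[p]
      in_tree[j] <- TRUE
      score[j] <- -Inf
      fresh <- adj_loc[[j]]
      fresh <- fresh[!in_tree[fresh]]
      score[fresh] <- dloc[fresh]
    }
  }
  structure(list(parent = parent, crest = crest, distance = distance),
            class = "crest_forest")
}

#' Prune crest trees and extract crest lines with gyral hinges
#'
#' Iteratively removes every leaf-to-nearest-bifurcation path whose
#' geodesic length is below `length_threshold`, until a fixpoint: pruning
#' a branch can expose a new short leaf path, so a single pass is not
#' stable. The surviving trunks are the gyral crest lines; vertices with
#' degree >= 3 in the pruned graph are gyral hinges, with `arm_count`
#' equal to their degree (3-hinges have exactly three arms).
#'
#' @param forest A `crest_forest` from [build_crest_trees()].
#' @param mesh The [surface_mesh] the forest lives on.
#' @param length_threshold Minimum branch length to survive pruning (mm).
#' @return An object of class `crest_graph`: list with `nodes` (surviving
#'   crest vertex ids), `edges` (2-column matrix), `hinges` (tibble:
#'   `vertex`, `arm_count`, `x`, `y`, `z`), `distance`, and
#'   `length_threshold`.
#' @export
prune_and_extract <- function(forest, mesh, length_threshold) {
  stopifnot(inherits(forest, "crest_forest"), length_threshold >= 0)
  crest <- forest$crest
  nloc <- length(crest)
  pos <- integer(n_vertices(mesh))
  pos[crest] <- seq_len(nloc)

  par_glob <- forest$parent[crest]
  has_par <- !is.na(par_glob) & par_glob > 0L
  e_from <- which(has_par)
  e_to <- pos[par_glob[has_par]]

  adj <- vector("list", nloc)
  for (i in seq_along(e_from)) {
    adj[[e_from[i]]] <- c(adj[[e_from[i]]], e_to[i])
    adj[[e_to[i]]] <- c(adj[[e_to[i]]], e_from[i])
  }
  elen <- function(a, b) {
    sqrt(sum((mesh$vertices[crest[a], ] - mesh$vertices[crest[b], ])^2))
  }

  alive <- rep(TRUE, nloc)
  deg <- vapply(adj, length, integer(1))
  repeat {
    leaves <- which(alive & deg == 1L)
    to_kill <- integer(0)
    for (leaf in leaves) {
      path <- leaf
      len <- 0
      cur <- leaf
      prev <- 0L
      repeat {
        nxt <- adj[[cur]]
        nxt <- nxt[alive[nxt] & nxt != prev]
        if (length(nxt) == 0L) { path <- NULL; break }  # isolated path end
        nxt <- nxt[1]
        len <- len + elen(cur, nxt)
        if (deg[nxt] >= 3L) break                       # reached bifurcation
        if (deg[nxt] == 1L) { path <- NULL; break }     # simple path component
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      if (!is.null(path) && len < length_threshold) {
        to_kill <- c(to_kill, path)
      }
    }
    to_kill <- unique(to_kill)
    to_kill <- to_kill[alive[to_kill]]
    if (length(to_kill) == 0L) break
    for (v in to_kill) {
      alive[v] <- FALSE
      for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
      deg[v] <- 0L
    }
  }

  keep_edge <- alive[e_from] & alive[e_to]
  edges <- cbind(crest[e_from[keep_edge]], crest[e_to[keep_edge]])
  nodes <- crest[alive]
  hinge_loc <- which(alive & deg >= 3L)
  hv <- crest[hinge_loc]
  hinges <- tibble(
    vertex = hv,
    arm_count = deg[hinge_loc],
    x = mesh$vertices[hv, 1],
    y = mesh$vertices[hv, 2],
    z = mesh$vertices[hv, 3]
  )
  hinges <- hinges[order(hinges$vertex), , drop = FALSE]
  structure(
    list(nodes = nodes, edges = edges, hinges = hinges,
         distance = forest$distance, length_threshold = length_threshold),
    class = "crest_graph"
  )
}

#' @export
print.crest_graph <- function(x, ...) {
  cat(sprintf(
    "<crest_graph> %d crest-line vertices, %d edges, %d hinges (%d 3-hinges)\n",
    length(x$nodes), nrow(x$edges), nrow(x$hinges),
    sum(x$hinges$arm_count == 3L)))
  invisible(x)
}

#' Full gyral hinge identification pipeline
#'
#' Composes the four stages: gyral altitude (taken from the mesh or
#' recomputed), watershed crest segmentation, crest distance transform
#' with tree marching, and branch pruning. Hinges are crest-line vertices
#' of degree >= 3; 3-hinges are those with exactly three arms.
#'
#' @param mesh A [surface_mesh].
#' @param altitude Per-vertex altitude; defaults to `mesh$altitude`, or is
#'   computed with [compute_gyral_altitude()] when absent.
#' @param level Crest threshold in mm (default 0, the mid-surface).
#' @param length_threshold Pruning threshold in mm; default 6 times the
#'   median mesh edge length.
#' @param smoothing_iters Passed to [compute_gyral_altitude()] when the
#'   altitude needs computing.
#' @return A `crest_graph` (see [prune_and_extract()]) with the
#'   `basin_segmentation` attached as `$seg`.
#' @export
detect_hinges <- function(mesh, altitude = NULL, level = 0,
                          length_threshold = NULL, smoothing_iters = 400) {
  if (is.null(altitude)) {
    altitude <- mesh$altitude %||% compute_gyral_altitude(mesh, smoothing_iters)
  }
  if (is.null(length_threshold)) {
    length_threshold <- 6 * median(mesh_edge_lengths(mesh))
  }
  seg <- watershed_segment(mesh, altitude, level)
  dist <- distance_transform_crest(mesh, seg)
  forest <- build_crest_trees(mesh, seg, dist)
  cg <- prune_and_extract(forest, mesh, length_threshold)
  cg$seg <- seg
  cg
}
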