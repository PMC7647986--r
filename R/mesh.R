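#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface in millimetre
#' coordinates, optionally carrying a per-vertex gyral altitude field
#' (signed mm, positive on the gyral side of the mid-surface).
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @param altitude Optional numeric vector of per-vertex altitudes (mm).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, altitude = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_hinge("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop_hinge("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_hinge("face indices out of range")
  }
  if (!is.null(altitude)) {
    altitude <- as.numeric(altitude)
    if (length(altitude) != nrow(vertices)) {
      stop_hinge("altitude must have one value per vertex")
    }
  }
  structure(list(vertices = vertices, faces = faces, altitude = altitude),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$altitude)) ", with altitude" else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-face triangle areas (mm^2)
#' @param mesh A `surface_mesh`.
#' @return Numeric vector, one area per face.
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex areas: one third of the incident triangle areas (mm^2)
#' @param mesh A `surface_mesh`.
#' @return Numeric vector, one area per vertex (0 for isolated vertices).
#' @export
mesh_vertex_areas <- function(mesh) {
  fa <- mesh_face_areas(mesh)
  va <- numeric(n_vertices(mesh))
  if (length(fa) == 0L) return(va)
  idx <- as.vector(mesh$faces)
  w <- rep(fa / 3, 3L)
  rs <- rowsum(w, idx)
  va[as.integer(rownames(rs))] <- rs[, 1]
  va
}

#' Unique undirected mesh edges
#' @param mesh A `surface_mesh`.
#' @return Two-column integer matrix, each row an edge with i < j.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (as.numeric(e[, 1]) - 1) * n_vertices(mesh) + e[, 2]
  e[!duplicated(key), , drop = FALSE]
}

mesh_edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  v <- mesh$vertices
  sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                  v[edges[, 2], , drop = FALSE])^2))
}

# igraph over the mesh edge graph, edge weight = Euclidean edge length (mm)
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  nv <- n_vertices(mesh)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  igraph::E(g)$weight <- mesh_edge_lengths(mesh, e)
  g
}

# adjacency list over vertices (list of integer neighbor vectors)
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  adj <- vector("list", nv)
  s <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adj[as.integer(names(s))] <- lapply(s, as.integer)
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer(0))
  adj
}

#' Area-weighted per-vertex normals
#' @param mesh A `surface_mesh`.
#' @return Numeric matrix of unit normals, one row per vertex.
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- n_vertices(mesh)
  nrm <- matrix(0, nv, 3)
  if (nrow(f) > 0L) {
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    for (k in 1:3) {
      rs <- rowsum(cr, f[, k])
      ids <- as.integer(rownames(rs))
      nrm[ids, ] <- nrm[ids, ] + rs
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Build a regular triangulated sheet in the z = 0 plane
#'
#' Grid of `nx` by `ny` vertices with the given spacing; each grid cell is
#' split into two triangles. If `height` is supplied it is used as the z
#' coordinate (and stored as the altitude field).
#'
#' @param nx,ny Number of vertices along x and y.
#' @param spacing Grid spacing (mm).
#' @param height Optional per-vertex z value, length `nx * ny`.
#' @return A `surface_mesh`.
#' @export
mesh_grid_sheet <- function(nx, ny, spacing = 1, height = NULL) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  vx <- rep(xs, times = ny)
  vy <- rep(ys, each = nx)
  vz <- if (is.null(height)) numeric(nx * ny) else as.numeric(height)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f1 <- cbind(id(i, j), id(i + 1L, j), id(i, j + 1L))
  f2 <- cbind(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  surface_mesh(cbind(vx, vy, vz), rbind(f1, f2),
               altitude = if (is.null(height)) NULL else vz)
}

#' Total surface area (mm^2)
#' @param mesh A `surface_mesh`.
#' @return Scalar area.
#' @export
mesh_total_area <- function(mesh) sum(mesh_face_areas(mesh))
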