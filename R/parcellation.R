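#' Partition a surface into connected patches of grossly equal area
#'
#' Seeds are chosen by farthest-point sampling on the mesh edge graph
#' (geodesic distances); patches then grow by balanced region growing: at
#' every step the patch with the smallest accumulated area claims the
#' unassigned frontier vertex closest (Euclidean) to its seed. Growth from
#' the frontier keeps every patch edge-connected, and smallest-first
#' claiming keeps areas within a narrow band of the mean. Deterministic
#' given the seed.
#'
#' @param mesh A [surface_mesh].
#' @param n_patches Number of patches (1 <= n_patches <= vertex count).
#' @param seed Integer seed (controls the first farthest-point sample).
#' @return An object of class `parcellation`: list with `patch_id`
#'   (per-vertex integer in 1..n_patches), `n_patches`, `patch_area`
#'   (mm^2 per patch), and `seed_vertices`.
#' @export
equal_area_parcellate <- function(mesh, n_patches, seed = 1) {
  nv <- n_vertices(mesh)
  if (n_patches < 1 || n_patches > nv) {
    stop_hinge("n_patches must be between 1 and the vertex count")
  }
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L) {
    stop_hinge("mesh edge graph must be connected for parcellation")
  }
  va <- mesh_vertex_areas(mesh)
  adj <- mesh_adjacency(mesh)

  seeds <- integer(n_patches)
  seeds[1] <- with_seed(seed, sample.int(nv, 1))
  if (n_patches > 1) {
    dmin <- as.vector(igraph::distances(g, v = seeds[1]))
    for (k in 2:n_patches) {
      seeds[k] <- which.max(dmin)
      dmin <- pmin(dmin, as.vector(igraph::distances(g, v = seeds[k])))
    }
  }

  assigned <- integer(nv)
  area <- numeric(n_patches)
  frontier <- vector("list", n_patches)
  for (k in seq_len(n_patches)) {
    assigned[seeds[k]] <- k
    area[k] <- va[seeds[k]]
    frontier[[k]] <- adj[[seeds[k]]]
  }
  open <- rep(TRUE, n_patches)
  sv <- mesh$vertices
  n_left <- nv - n_patches
  while (n_left > 0L) {
    a <- ifelse(open, area, Inf)
    p <- which.min(a)
    if (!is.finite(a[p])) stop_hinge("parcellation stalled: disconnected region")
    fr <- frontier[[p]]
    fr <- fr[assigned[fr] == 0L]
    if (length(fr) == 0L) {
      frontier[[p]] <- integer(0)
      open[p] <- FALSE
      next
    }
    fr <- unique(fr)
    d2 <- (sv[fr, 1] - sv[seeds[p], 1])^2 +
      (sv[fr, 2] - sv[seeds[p], 2])^2 +
      (sv[fr, 3] - sv[seeds[p], 3])^2
    v <- fr[order(d2, fr)][1]
    assigned[v] <- p
    area[p] <- area[p] + va[v]
    nb <- adj[[v]]
    frontier[[p]] <- c(fr[fr != v], nb[assigned[nb] == 0L])
    n_left <- n_left - 1L
  }

  assigned <- rebalance_patches(assigned, n_patches, va, adj)

  structure(
    list(patch_id = assigned, n_patches = as.integer(n_patches),
         patch_area = as.vector(rowsum(va, assigned)),
         seed_vertices = seeds),
    class = "parcellation"
  )
}

# area-diffusion rebalancing: sweep patches from smallest to largest,
# letting each take one boundary vertex from a sufficiently larger
# neighbour when the donor stays connected; iterate sweeps to fixpoint
rebalance_patches <- function(assigned, n_patches, va, adj,
                              max_sweeps = 200L) {
  if (n_patches < 2L) return(assigned)
  area <- as.vector(rowsum(va, assigned))
  patch_vs <- split(seq_along(assigned), assigned)
  stays_connected <- function(vs, drop_v) {
    rest <- vs[vs != drop_v]
    if (length(rest) <= 1L) return(length(rest) == 1L)
    seen <- logical(length(rest))
    seen[1] <- TRUE
    frontier <- rest[1]
    while (length(frontier) > 0L) {
      nxt <- match(unlist(adj[frontier]), rest)
      nxt <- unique(nxt[!is.na(nxt)])
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- rest[nxt]
    }
    all(seen)
  }
  amean <- mean(area)
  for (sw in seq_len(max_sweeps)) {
    any_moved <- FALSE
    for (s in order(area, seq_len(n_patches))) {
      svs <- patch_vs[[s]]
      ring <- setdiff(unique(unlist(adj[svs])), svs)
      if (length(ring) == 0L) next
      donors <- assigned[ring]
      ok <- (area[donors] - area[s] > va[ring] + 0.01) |
        (area[donors] > amean + va[ring] & area[s] < amean - va[ring])
      if (!any(ok)) next
      ring <- ring[ok]
      donors <- donors[ok]
      for (ii in order(-area[donors], ring)) {
        v <- ring[ii]
        b <- donors[ii]
        if (stays_connected(patch_vs[[b]], v)) {
          assigned[v] <- s
          patch_vs[[s]] <- c(patch_vs[[s]], v)
          patch_vs[[b]] <- patch_vs[[b]][patch_vs[[b]] != v]
          area[s] <- area[s] + va[v]
          area[b] <- area[b] - va[v]
          any_moved <- TRUE
          break
        }
      }
    }
    if (!any_moved) break
  }
  equalize_chains(assigned, n_patches, va, adj)
}

# shift one vertex of area along a shortest patch-graph path from a
# rich patch down to the poorest patch (and from the richest up to a
# poor one), so deficits trapped behind near-mean patches still fill
equalize_chains <- function(assigned, n_patches, va, adj,
                            target_ratio = 1.35, max_chains = 4L * n_patches) {
  area <- as.vector(rowsum(va, assigned))
  patch_vs <- split(seq_along(assigned), assigned)
  stays_connected <- function(vs, drop_v) {
    rest <- vs[vs != drop_v]
    if (length(rest) <= 1L) return(length(rest) == 1L)
    seen <- logical(length(rest))
    seen[1] <- TRUE
    frontier <- rest[1]
    while (length(frontier) > 0L) {
      nxt <- match(unlist(adj[frontier]), rest)
      nxt <- unique(nxt[!is.na(nxt)])
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- rest[nxt]
    }
    all(seen)
  }
  edge_tails <- rep(seq_along(adj), lengths(adj))
  edge_heads <- unlist(adj)
  va_mean <- mean(va)
  patch_neighbors <- function() {
    pa <- assigned[edge_tails]
    pb <- assigned[edge_heads]
    keep <- pa != pb
    key <- unique((pa[keep] - 1) * n_patches + pb[keep])
    from <- ((key - 1) %/% n_patches) + 1
    to <- key - (from - 1) * n_patches
    s <- split(to, from)
    out <- vector("list", n_patches)
    out[as.integer(names(s))] <- s
    out[vapply(out, is.null, logical(1))] <- list(integer(0))
    out
  }
  move_one <- function(donor, receiver) {
    rv <- patch_vs[[receiver]]
    ring <- unique(unlist(adj[rv]))
    cand <- ring[assigned[ring] == donor]
    for (v in sort(cand)) {
      if (stays_connected(patch_vs[[donor]], v)) {
        assigned[v] <<- receiver
        patch_vs[[receiver]] <<- c(patch_vs[[receiver]], v)
        patch_vs[[donor]] <<- patch_vs[[donor]][patch_vs[[donor]] != v]
        area[receiver] <<- area[receiver] + va[v]
        area[donor] <<- area[donor] - va[v]
        return(TRUE)
      }
    }
    FALSE
  }
  blocked <- logical(n_patches)
  for (ch in seq_len(max_chains)) {
    amean <- mean(area)
    lo <- which.min(area + ifelse(blocked, Inf, 0))
    if (blocked[lo] || max(area) / min(area) <= target_ratio) break
    pn <- patch_neighbors()
    # BFS from the poorest patch to the nearest above-mean patch
    prev <- rep(NA_integer_, n_patches)
    visited <- logical(n_patches)
    visited[lo] <- TRUE
    q <- lo
    goal <- NA_integer_
    while (length(q) > 0L && is.na(goal)) {
      nq <- integer(0)
      for (p in q) {
        for (w in pn[[p]]) {
          if (!visited[w]) {
            visited[w] <- TRUE
            prev[w] <- p
            if (area[w] > amean + va_mean) {
              goal <- w
              break
            }
            nq <- c(nq, w)
          }
        }
        if (!is.na(goal)) break
      }
      q <- nq
    }
    if (is.na(goal)) { blocked[lo] <- TRUE; next }
    path <- goal
    while (path[length(path)] != lo) path <- c(path, prev[path[length(path)]])
    ok <- TRUE
    for (i in seq_len(length(path) - 1L)) {
      if (!move_one(path[i], path[i + 1L])) { ok <- FALSE; break }
    }
    if (!ok) blocked[lo] <- TRUE else blocked[] <- FALSE
  }
  assigned
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d patches, area %0.1f-%0.1f mm^2\n",
              x$n_patches, min(x$patch_area), max(x$patch_area)))
  invisible(x)
}

#' Label patches by cortical convolution class
#'
#' A patch more than half of whose area lies in sulcal basins is SULCAL;
#' among the remaining (gyral) patches, those touched by a gyral hinge
#' vertex are H3 (3-hinge patches) and the rest are H2 (2-hinge patches).
#' The sulcal rule is applied first, so a sulcal-majority patch stays
#' SULCAL even when a hinge falls inside it.
#'
#' @param parc A `parcellation`.
#' @param seg A `basin_segmentation` on the same mesh.
#' @param crest A `crest_graph` on the same mesh.
#' @param mesh The [surface_mesh] (for vertex areas).
#' @return A tibble with one row per patch: `patch`, `area_mm2`,
#'   `sulcal_fraction`, `hinge_count`, `class` (factor H3/H2/SULCAL).
#' @export
label_patches <- function(parc, seg, crest, mesh) {
  nv <- length(parc$patch_id)
  if (length(seg$basin_id) != nv) {
    stop_hinge("parcellation and segmentation vertex counts differ")
  }
  va <- mesh_vertex_areas(mesh)
  if (length(va) != nv) stop_hinge("mesh vertex count mismatch")
  np <- parc$n_patches
  sulc_area <- as.vector(rowsum(va * (seg$basin_id > 0L), parc$patch_id,
                                reorder = TRUE))
  sulcal_fraction <- sulc_area / parc$patch_area
  hinge_vertices <- crest$hinges$vertex
  hinge_count <- tabulate(parc$patch_id[hinge_vertices], nbins = np)
  cls <- ifelse(sulcal_fraction > 0.5, "SULCAL",
                ifelse(hinge_count >= 1L, "H3", "H2"))
  tibble(
    patch = seq_len(np),
    area_mm2 = parc$patch_area,
    sulcal_fraction = sulcal_fraction,
    hinge_count = as.integer(hinge_count),
    class = factor(cls, levels = c("H3", "H2", "SULCAL"))
  )
}
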