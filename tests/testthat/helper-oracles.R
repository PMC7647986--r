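# Independent brute-force oracles used to check the package's graph
# metrics and mesh distances. These deliberately use different
# algorithms from the implementation (Floyd-Warshall with explicit path
# counting instead of Dijkstra/Brandes; exhaustive loops instead of
# matrix algebra).

# plain Floyd-Warshall distances on edge lengths 1/w
fw_dist <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      alt <- D[i, k] + D[k, ]
      upd <- alt < D[i, ]
      D[i, upd] <- alt[upd]
    }
  }
  D
}

# Floyd-Warshall with shortest-path counting (each path attributed to
# its maximal intermediate vertex, so every path is counted once)
fw_paths <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  S <- ifelse(W > 0, 1, 0)
  diag(S) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k) next
      alt <- D[i, k] + D[k, ]
      shorter <- alt < D[i, ] - 1e-12
      equal <- is.finite(alt) & abs(alt - D[i, ]) <= 1e-12
      shorter[c(i, k)] <- FALSE
      equal[c(i, k)] <- FALSE
      if (any(shorter)) {
        D[i, shorter] <- alt[shorter]
        S[i, shorter] <- S[i, k] * S[k, shorter]
      }
      if (any(equal)) {
        S[i, equal] <- S[i, equal] + S[i, k] * S[k, equal]
      }
    }
  }
  list(D = D, S = S)
}

oracle_betweenness <- function(W) {
  fp <- fw_paths(W)
  D <- fp$D
  S <- fp$S
  n <- nrow(W)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
            abs(D[s, i] + D[i, t] - D[s, t]) <= 1e-12) {
          b[i] <- b[i] + S[s, i] * S[i, t] / S[s, t]
        }
      }
    }
  }
  b
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    d <- length(nb)
    if (d < 2) next
    FD <- fw_dist(W[nb, nb, drop = FALSE])
    tot <- 0
    for (a in seq_len(d)) {
      for (b2 in seq_len(d)) {
        if (a == b2) next
        p <- FD[a, b2]
        if (is.finite(p) && p > 0) {
          tot <- tot + (W[i, nb[a]] * W[i, nb[b2]] / p)^(1 / 3)
        }
      }
    }
    out[i] <- tot / (d * (d - 1))
  }
  out
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  Ws <- W / max(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    d <- length(nb)
    if (d < 2) next
    tot <- 0
    for (a in seq_len(d - 1)) {
      for (b2 in (a + 1):d) {
        j <- nb[a]
        k <- nb[b2]
        if (W[j, k] > 0) {
          tot <- tot + 2 * (Ws[i, j] * Ws[j, k] * Ws[k, i])^(1 / 3)
        }
      }
    }
    out[i] <- tot / (d * (d - 1))
  }
  out
}

oracle_participation <- function(W, memb) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    d <- length(nb)
    if (d == 0) next
    frac <- 0
    for (m in unique(memb)) {
      frac <- frac + (sum(memb[nb] == m) / d)^2
    }
    out[i] <- 1 - frac
  }
  out
}

# O(n^2) Dijkstra from a source set over an explicit edge list
oracle_multisource_dijkstra <- function(n, edges, lengths, sources) {
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- logical(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]
    b <- edges[r, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, lengths[r]))
    adj[[b]] <- rbind(adj[[b]], c(a, lengths[r]))
  }
  for (it in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        nd <- dist[u] + adj[[u]][r, 2]
        if (nd < dist[v]) dist[v] <- nd
      }
    }
  }
  dist
}

random_weighted_net <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::runif(n * n) < p, n, n)
    W <- matrix(stats::runif(n * n, 0.5, 3), n, n) * A
    W[lower.tri(W, diag = TRUE)] <- 0
    weighted_network(W + t(W))
  })
}

# recovery bookkeeping for planted hinge junctions
hinge_match_stats <- function(cg, truth, tol_hit = 2, tol_spur = 5) {
  det <- as.matrix(cg$hinges[cg$hinges$arm_count >= 3, c("x", "y")])
  tru <- truth$hinge_locations[, 1:2, drop = FALSE]
  hit <- 0
  if (nrow(tru) > 0 && nrow(det) > 0) {
    for (i in seq_len(nrow(tru))) {
      d <- sqrt(rowSums((det - matrix(tru[i, ], nrow(det), 2,
                                      byrow = TRUE))^2))
      if (min(d) <= tol_hit) hit <- hit + 1
    }
  }
  spur <- 0
  if (nrow(det) > 0) {
    for (i in seq_len(nrow(det))) {
      d <- if (nrow(tru) > 0) {
        sqrt(rowSums((tru - matrix(det[i, ], nrow(tru), 2, byrow = TRUE))^2))
      } else Inf
      if (min(d) > tol_spur) spur <- spur + 1
    }
  }
  c(n_true = nrow(tru), hit = hit, n_det = nrow(det), spur = spur)
}

# strip mesh: crest band of `width` rows flanked by basins, unit spacing
strip_mesh <- function(nx = 20, width = 5, pad = 2) {
  ny <- width + 2 * pad
  alt <- ifelse(rep(seq_len(ny), each = nx) %in%
                  (pad + seq_len(width)), 1, -1)
  mesh_grid_sheet(nx, ny, 1, height = alt)
}
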