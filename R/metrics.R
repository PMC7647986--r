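#' Nodal degree
#'
#' Number of nodes connected to each node: the row sums of the binary
#' adjacency matrix.
#'
#' @param net A [weighted_network].
#' @return Integer vector of per-node degrees.
#' @export
net_degree <- function(net) as.integer(rowSums(net$weights > 0))

#' Nodal strength
#'
#' Sum of the weights of a node's connections.
#'
#' @param net A [weighted_network].
#' @return Numeric vector of per-node strengths.
#' @export
net_strength <- function(net) rowSums(net$weights)

#' Nodal betweenness centrality
#'
#' Unnormalised sum over unordered node pairs of the fraction of shortest
#' paths passing through each node. Shortest paths are computed on edge
#' lengths `1 / w_ij` (the standard connectomics weight-to-length map);
#' with `binarize = TRUE` every edge has unit length instead.
#' Disconnected pairs contribute nothing.
#'
#' @param net A [weighted_network].
#' @param binarize Use unit edge lengths instead of `1 / w`.
#' @return Numeric vector of per-node betweenness values.
#' @export
net_betweenness <- function(net, binarize = FALSE) {
  g <- net_graph(net)
  if (igraph::ecount(g) == 0L) return(numeric(net$n_nodes))
  len <- if (binarize) rep(1, igraph::ecount(g)) else 1 / igraph::E(g)$weight
  as.vector(igraph::betweenness(g, directed = FALSE, weights = len))
}

#' Nodal local efficiency (weighted)
#'
#' For node i with neighbours N_i, averages
#' `(w_ij * w_ih / p_jh(N_i))^(1/3)` over ordered pairs of distinct
#' neighbours, where `p_jh(N_i)` is the shortest-path length between j
#' and h through the subgraph induced by N_i (edge lengths `1 / w`,
#' original weights, i itself excluded). Pairs with no such path
#' contribute 0, and nodes with fewer than two neighbours get 0.
#'
#' @param net A [weighted_network].
#' @return Numeric vector of per-node efficiencies.
#' @export
net_local_efficiency <- function(net) {
  W <- net$weights
  n <- net$n_nodes
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    d <- length(nb)
    if (d < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    if (igraph::ecount(gs) > 0L) {
      P <- igraph::distances(gs, weights = 1 / igraph::E(gs)$weight,
                             algorithm = "dijkstra")
    } else {
      P <- matrix(Inf, d, d)
      diag(P) <- 0
    }
    terms <- (outer(W[i, nb], W[i, nb]) / P)^(1 / 3)
    diag(terms) <- 0
    terms[!is.finite(terms)] <- 0
    out[i] <- sum(terms) / (d * (d - 1))
  }
  out
}

#' Nodal clustering coefficient (Onnela)
#'
#' Geometric mean of triangle weights after scaling all weights by the
#' network maximum: `c_i = diag((W~^(1/3))^3)_i / (d_i (d_i - 1))`,
#' zero for nodes of degree < 2.
#'
#' @param net A [weighted_network].
#' @return Numeric vector of per-node clustering coefficients in `[0, 1]`.
#' @export
net_clustering <- function(net) {
  Ws <- net_scaled_weights(net)  # errors if all weights are zero
  K <- Ws^(1 / 3)
  cube <- K %*% K %*% K
  d <- rowSums(Ws > 0)
  out <- numeric(net$n_nodes)
  ok <- d >= 2
  out[ok] <- diag(cube)[ok] / (d[ok] * (d[ok] - 1))
  out
}

#' Modularity partition (Louvain, resolution gamma)
#'
#' Greedy multi-level modularity maximisation on the weighted graph at
#' resolution `gamma`; the module count is determined by the
#' optimisation, not fixed in advance. Deterministic given the seed.
#'
#' @param net A [weighted_network].
#' @param gamma Resolution parameter (> 0). Default 1.
#' @param seed Integer seed for the optimiser.
#' @return An object of class `module_partition`: list with `module_id`
#'   (integer per node, contiguous from 1), `n_modules`, `gamma`, `Q`
#'   (modularity at resolution `gamma`), `seed`.
#' @export
partition_modules <- function(net, gamma = 1, seed = 1) {
  stopifnot(gamma > 0)
  if (net$n_nodes == 0L || sum(net$weights) == 0) {
    stop_hinge("cannot partition an empty graph")
  }
  g <- net_graph(net)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = gamma))
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, sort(unique(memb)))
  structure(
    list(module_id = memb, n_modules = max(memb), gamma = gamma,
         Q = igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                                resolution = gamma),
         seed = seed),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.3f (gamma = %g)\n",
              x$n_modules, x$Q, x$gamma))
  invisible(x)
}

#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble(n_modules = x$n_modules, Q = x$Q, gamma = x$gamma, seed = x$seed)
}

#' Participation coefficient
#'
#' `p_i = 1 - sum_m (d_i(m) / d_i)^2`, where `d_i(m)` counts the
#' connections from node i to module m. Nodes with no connections get 0.
#' Values near 0 mark provincial hubs; larger values mark connector hubs.
#'
#' @param net A [weighted_network].
#' @param partition A `module_partition` covering all nodes.
#' @return Numeric vector of per-node participation coefficients.
#' @export
net_participation <- function(net, partition) {
  memb <- partition$module_id
  if (length(memb) != net$n_nodes) {
    stop_hinge("partition must cover all nodes")
  }
  A <- net$weights > 0
  d <- rowSums(A)
  M <- max(memb)
  Imat <- matrix(0, net$n_nodes, M)
  Imat[cbind(seq_len(net$n_nodes), memb)] <- 1
  dm <- A %*% Imat
  p <- 1 - rowSums((dm / pmax(d, 1))^2)
  p[d == 0] <- 0
  p
}

#' Compute all six nodal metrics for one network
#'
#' Degree, strength, betweenness, local efficiency, Onnela clustering and
#' participation coefficient (on a fresh Louvain partition at resolution
#' `gamma`), with node classes attached when the network carries labels.
#'
#' @param net A [weighted_network].
#' @param gamma Modularity resolution (default 1).
#' @param seed Seed for the partition.
#' @param subject_id Optional subject identifier column.
#' @return A tibble with one row per node: `subject`, `node`, `class`,
#'   `degree`, `strength`, `betweenness`, `efficiency`, `clustering`,
#'   `participation`, `module`.
#' @export
compute_all_metrics <- function(net, gamma = 1, seed = 1, subject_id = NA) {
  part <- partition_modules(net, gamma = gamma, seed = seed)
  tibble(
    subject = subject_id,
    node = seq_len(net$n_nodes),
    class = if (is.null(net$labels)) NA_character_ else net$labels,
    degree = net_degree(net),
    strength = net_strength(net),
    betweenness = net_betweenness(net),
    efficiency = net_local_efficiency(net),
    clustering = net_clustering(net),
    participation = net_participation(net, part),
    module = part$module_id
  )
}

hinge_metric_names <- function() {
  c("degree", "strength", "betweenness", "efficiency", "clustering",
    "participation")
}
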