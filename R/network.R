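#' Weighted patch-level structural network
#'
#' Symmetric nonnegative weight matrix with zero diagonal; the binary
#' adjacency and the max-scaled weights used by the Onnela clustering
#' coefficient are derived on demand, never stored separately.
#'
#' @param weights Symmetric nonnegative numeric matrix, zero diagonal.
#' @param labels Optional per-node class labels (e.g. H3/H2/SULCAL).
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop_hinge("weights must be square")
  if (any(!is.finite(weights))) stop_hinge("weights must be finite")
  if (any(weights < 0)) stop_hinge("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop_hinge("weights must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (!is.null(labels)) {
    if (length(labels) != nrow(weights)) {
      stop_hinge("labels must have one entry per node")
    }
    labels <- as.character(labels)
  }
  structure(list(weights = weights, n_nodes = nrow(weights), labels = labels),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges%s\n",
              x$n_nodes, sum(x$weights > 0) / 2,
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

net_adjacency <- function(net) (net$weights > 0) * 1

net_scaled_weights <- function(net) {
  mx <- max(net$weights)
  if (mx == 0) stop_hinge("all weights are zero")
  net$weights / mx
}

# igraph view; edge attribute `weight` = connection weight w_ij
net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
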