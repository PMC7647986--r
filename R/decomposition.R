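#' s-core of a weighted network
#'
#' The s-core is the maximal subgraph in which every surviving node keeps
#' a summed connection weight of at least `s`: nodes whose residual
#' strength falls below `s` are removed iteratively until a fixpoint.
#' With unit weights and integer `s` this reduces to the classical
#' k-core. The `edge_prune` variant first deletes individual edges with
#' weight below `s` at every round before applying the strength rule.
#'
#' @param net A [weighted_network].
#' @param s Core level (>= 0).
#' @param edge_prune Also prune individual edges lighter than `s`
#'   (default `FALSE`).
#' @return List with `preserved` (sorted node indices) and `mask`
#'   (logical per node). The survivor set may be empty.
#' @export
s_core <- function(net, s, edge_prune = FALSE) {
  stopifnot(s >= 0)
  W <- net$weights
  alive <- rep(TRUE, net$n_nodes)
  repeat {
    if (edge_prune) W[W < s] <- 0
    str <- rowSums(W)
    drop <- alive & str < s & (s > 0)
    if (!any(drop)) break
    W[drop, ] <- 0
    W[, drop] <- 0
    alive[drop] <- FALSE
  }
  list(preserved = which(alive), mask = alive)
}

#' Single-pass nodal strength decomposition
#'
#' Deletes the nodes whose strength on the full network is below `s`; in
#' contrast to [s_core()] the strengths are not recomputed after removal.
#'
#' @param net A [weighted_network].
#' @param s Strength level (>= 0).
#' @return List with `preserved` and `mask` as in [s_core()].
#' @export
strength_decompose <- function(net, s) {
  stopifnot(s >= 0)
  str <- net_strength(net)
  mask <- if (s > 0) str >= s else rep(TRUE, net$n_nodes)
  list(preserved = which(mask), mask = mask)
}

default_s_levels <- function(net, n_levels = 50) {
  seq(0, max(net_strength(net)), length.out = n_levels)
}

decompose_masks <- function(net, s_levels, method, edge_prune = FALSE) {
  vapply(s_levels, function(s) {
    if (method == "s_core") s_core(net, s, edge_prune = edge_prune)$mask
    else strength_decompose(net, s)$mask
  }, logical(net$n_nodes))
}

#' Class ratio curves along a decomposition
#'
#' For each level `s`, the fraction of preserved nodes belonging to each
#' convolution class (H3, H2, SULCAL). At level 0 the ratios equal the
#' intact class fractions; levels with no survivors are marked `NA`.
#'
#' @param net A [weighted_network].
#' @param labels Per-node class labels (H3/H2/SULCAL); defaults to the
#'   network's own labels.
#' @param s_levels Ascending numeric levels; default 50 levels linear
#'   from 0 to the maximum nodal strength.
#' @param method `"s_core"` or `"strength"`.
#' @param edge_prune Passed to [s_core()].
#' @return A tibble of class `ratio_curves`: columns `s`, `n_preserved`,
#'   `ratio_h3`, `ratio_h2`, `ratio_sulcal`, `method`.
#' @export
ratio_curves <- function(net, labels = net$labels, s_levels = NULL,
                         method = c("s_core", "strength"),
                         edge_prune = FALSE) {
  method <- match.arg(method)
  if (is.null(labels)) stop_hinge("node labels are required")
  labels <- as.character(labels)
  if (is.null(s_levels)) s_levels <- default_s_levels(net)
  if (is.unsorted(s_levels)) stop_hinge("s_levels must be ascending")
  masks <- decompose_masks(net, s_levels, method, edge_prune)
  n_pres <- colSums(masks)
  count <- function(cls) as.vector(crossprod(masks, labels == cls))
  out <- tibble(
    s = s_levels,
    n_preserved = as.integer(n_pres),
    ratio_h3 = ifelse(n_pres > 0, count("H3") / n_pres, NA_real_),
    ratio_h2 = ifelse(n_pres > 0, count("H2") / n_pres, NA_real_),
    ratio_sulcal = ifelse(n_pres > 0, count("SULCAL") / n_pres, NA_real_),
    method = method
  )
  class(out) <- c("ratio_curves", class(out))
  out
}

#' Cohort mean and sd of ratio curves
#'
#' Averages per-subject ratio curves (computed on a shared level grid)
#' across subjects, with cross-subject standard deviations per level.
#'
#' @param curves_list List of `ratio_curves` tibbles on identical
#'   `s_levels`.
#' @return Tibble with per-level mean and sd of the H3 and H2 ratios.
#' @export
cohort_ratio_curves <- function(curves_list) {
  stopifnot(length(curves_list) >= 1)
  all <- bind_rows(lapply(seq_along(curves_list), function(i) {
    mutate(as_tibble(curves_list[[i]]), subject = i)
  }))
  all |>
    group_by(.data$s, .data$method) |>
    summarise(
      mean_h3 = mean(.data$ratio_h3, na.rm = TRUE),
      sd_h3 = sd(.data$ratio_h3, na.rm = TRUE),
      mean_h2 = mean(.data$ratio_h2, na.rm = TRUE),
      sd_h2 = sd(.data$ratio_h2, na.rm = TRUE),
      n_subjects = sum(!is.na(.data$ratio_h3)),
      .groups = "drop"
    )
}

#' Curve-crossing permutation test
#'
#' Tests whether the H3 ratio curve surpassing the H2 curve somewhere
#' along the decomposition could arise by chance: node class labels are
#' shuffled (class sizes preserved) `n_perm` times, and the crossing
#' event (some level with strictly more H3 than H2 survivors among the
#' preserved nodes) is recorded for each shuffle. The survivor sets do
#' not depend on the labels, so they are computed once. When the
#' observed curves do cross, `p = (1 + #events) / (1 + n_perm)` — the
#' chance of a crossing under label exchange; when they do not, `p = 1`
#' (no evidence), with the raw null crossing rate always reported as
#' `null_crossing_rate`.
#'
#' @param net A [weighted_network].
#' @param labels Per-node class labels; both H3 and H2 must be present.
#' @param s_levels Level grid (default as in [ratio_curves()]).
#' @param method `"s_core"` or `"strength"`.
#' @param n_perm Number of label permutations (>= 1). Default 1000.
#' @param seed Integer seed.
#' @return An object of class `hinge_perm_test`: list with `p_value`,
#'   `observed_event`, `n_perm`, `method`, `statistic` (description).
#' @export
crossing_permutation_test <- function(net, labels = net$labels,
                                      s_levels = NULL,
                                      method = c("s_core", "strength"),
                                      n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1)
  if (is.null(labels)) stop_hinge("node labels are required")
  labels <- as.character(labels)
  if (!any(labels == "H3") || !any(labels == "H2")) {
    stop_hinge("degenerate labels: need both H3 and H2 nodes")
  }
  if (is.null(s_levels)) s_levels <- default_s_levels(net)
  masks <- decompose_masks(net, s_levels, method)   # levels x: n x L
  crossing_event <- function(lab) {
    h3 <- as.vector(crossprod(masks, lab == "H3"))
    h2 <- as.vector(crossprod(masks, lab == "H2"))
    any(h3 > h2 & colSums(masks) > 0)
  }
  observed <- crossing_event(labels)
  events <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      crossing_event(sample(labels))
    }, logical(1))
  })
  p_null <- (1 + sum(events)) / (1 + n_perm)
  structure(
    list(p_value = if (observed) p_null else 1,
         null_crossing_rate = p_null,
         observed_event = observed, n_perm = n_perm, method = method,
         statistic = "exists s with ratio_h3 > ratio_h2"),
    class = "hinge_perm_test"
  )
}

#' Cohort-level curve-crossing permutation test
#'
#' Group-mean version of [crossing_permutation_test()]: the crossing
#' event is evaluated on the cross-subject mean ratio curves (as the
#' curves are reported for a cohort), which suppresses the single-node
#' noise of individual curve tails. Per permutation, every subject's
#' node labels are shuffled independently (class sizes preserved), the
#' per-subject ratio curves are recomputed on a shared level grid, and
#' the event is a level where the mean H3 ratio strictly exceeds the
#' mean H2 ratio. `p = (1 + #events) / (1 + n_perm)`.
#'
#' @param networks List of [weighted_network] objects (one per subject),
#'   each carrying H3/H2/SULCAL labels.
#' @param s_levels Shared ascending level grid; default 50 levels from 0
#'   to the largest nodal strength in the cohort.
#' @param method `"s_core"` or `"strength"`.
#' @param n_perm Number of permutations (>= 1). Default 1000.
#' @param seed Integer seed.
#' @return A `hinge_perm_test` with `p_value`, `observed_event`,
#'   `n_perm`, `method`.
#' @export
cohort_crossing_test <- function(networks, s_levels = NULL,
                                 method = c("s_core", "strength"),
                                 n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(networks) >= 1, n_perm >= 1)
  labels <- lapply(networks, function(net) {
    if (is.null(net$labels)) stop_hinge("networks must carry labels")
    as.character(net$labels)
  })
  if (is.null(s_levels)) {
    smax <- max(vapply(networks, function(net) max(net_strength(net)),
                       numeric(1)))
    s_levels <- seq(0, smax, length.out = 50)
  }
  L <- length(s_levels)
  masks <- lapply(networks, decompose_masks, s_levels = s_levels,
                  method = method)
  n_pres <- lapply(masks, colSums)

  # the group-mean curve is only meaningful where every subject still
  # preserves at least one node; beyond that the "mean" is one subject
  complete <- Reduce(`&`, lapply(n_pres, function(x) x > 0))
  mean_event <- function(lab_list) {
    h3sum <- h2sum <- numeric(L)
    for (s in seq_along(masks)) {
      h3 <- as.vector(crossprod(masks[[s]], lab_list[[s]] == "H3"))
      h2 <- as.vector(crossprod(masks[[s]], lab_list[[s]] == "H2"))
      np <- pmax(n_pres[[s]], 1)
      h3sum <- h3sum + h3 / np
      h2sum <- h2sum + h2 / np
    }
    any(complete & h3sum > h2sum)
  }
  observed <- mean_event(labels)
  events <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mean_event(lapply(labels, sample))
    }, logical(1))
  })
  p_null <- (1 + sum(events)) / (1 + n_perm)
  structure(
    list(p_value = if (observed) p_null else 1,
         null_crossing_rate = p_null,
         observed_event = observed, n_perm = n_perm, method = method,
         statistic = "exists s with mean ratio_h3 > mean ratio_h2"),
    class = "hinge_perm_test"
  )
}
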