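#' Specification for a synthetic network cohort with planted hubs
#'
#' Describes a cohort of weighted modular networks in which a designated
#' minority of nodes (the H3 class) receives boosted expected degree,
#' edge weight and cross-module connection probability, emulating the
#' hub-like contrast between 3-hinge and 2-hinge cortical patches. With
#' `hub_degree_boost = 0` and `hub_crossmodule_prob` equal to the
#' background cross-module probability the H3 and H2 classes are
#' exchangeable (a null cohort).
#'
#' @param n_subjects Number of subjects (networks).
#' @param n_patches Nodes per network.
#' @param n_h3,n_h2 Numbers of H3 and H2 nodes (`n_h3 + n_h2 <=
#'   n_patches`); the remainder is SULCAL.
#' @param hub_degree_boost Nonnegative factor: H3-incident edge
#'   probabilities and weights are multiplied by `1 + hub_degree_boost`.
#' @param hub_crossmodule_prob Probability of a cross-module edge at an
#'   H3 node (background nodes use `p_out`).
#' @param n_modules Number of planted modules.
#' @param noise_sd Lognormal sd of multiplicative weight noise.
#' @param seed Master seed; per-subject streams come from
#'   [derive_seed()].
#' @param p_in,p_out Background within/cross-module edge probabilities.
#' @param w_in,w_out Baseline within/cross-module edge weights.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, n_patches = 150, n_h3 = 25,
                        n_h2 = 75, hub_degree_boost = 2,
                        hub_crossmodule_prob = 0.25, n_modules = 4,
                        noise_sd = 0.3, seed = 1,
                        p_in = 0.35, p_out = 0.05, w_in = 8, w_out = 4) {
  stopifnot(n_subjects >= 1, n_patches >= 2, n_h3 >= 0, n_h2 >= 0,
            hub_degree_boost >= 0, noise_sd >= 0, n_modules >= 1)
  if (n_h3 + n_h2 > n_patches) stop_hinge("n_h3 + n_h2 exceeds n_patches")
  if (hub_crossmodule_prob < 0 || hub_crossmodule_prob > 1 ||
      p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop_hinge("probabilities must lie in [0, 1]")
  }
  if (n_modules > n_patches) stop_hinge("n_modules exceeds n_patches")
  structure(
    list(n_subjects = n_subjects, n_patches = n_patches, n_h3 = n_h3,
         n_h2 = n_h2, hub_degree_boost = hub_degree_boost,
         hub_crossmodule_prob = hub_crossmodule_prob, n_modules = n_modules,
         noise_sd = noise_sd, seed = seed, p_in = p_in, p_out = p_out,
         w_in = w_in, w_out = w_out),
    class = "cohort_spec"
  )
}

#' Generate a cohort of weighted modular networks with planted hubs
#'
#' Each subject's network is drawn from a stochastic block model with
#' `n_modules` planted modules; H3 nodes get their edge probabilities and
#' weights multiplied by `1 + hub_degree_boost` and their cross-module
#' edge probability replaced by `hub_crossmodule_prob`, so degree,
#' strength, betweenness and participation contrasts are all exercised.
#' Node classes and module assignments are drawn once from the master
#' seed and shared across subjects; subject-level randomness uses
#' independent counter-derived streams, so cohorts are order-independent.
#'
#' @param spec A [cohort_spec()].
#' @return A list of length `n_subjects`; each element has `network`
#'   (a [weighted_network] carrying labels), `labels` (per-node factor),
#'   `module` (planted module ids), and `hub_ids` (H3 node indices).
#' @export
gen_network_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patches
  layout <- with_seed(derive_seed(spec$seed, 0), {
    module <- rep(seq_len(spec$n_modules), length.out = n)[sample.int(n)]
    ids <- sample.int(n)
    list(module = module,
         h3 = sort(ids[seq_len(spec$n_h3)]),
         h2 = sort(ids[spec$n_h3 + seq_len(spec$n_h2)]))
  })
  labels <- rep("SULCAL", n)
  labels[layout$h3] <- "H3"
  labels[layout$h2] <- "H2"
  is_h3 <- labels == "H3"

  same_mod <- outer(layout$module, layout$module, "==")
  h3_pair <- outer(is_h3, is_h3, "|")
  # boost acts per H3 endpoint, so hub-hub edges form a rich club whose
  # weights survive core decomposition on their own
  boost <- (1 + spec$hub_degree_boost)^(outer(is_h3, is_h3, "+"))
  prob <- ifelse(same_mod, spec$p_in, spec$p_out)
  prob[h3_pair & !same_mod] <- spec$hub_crossmodule_prob
  prob <- matrix(pmin(prob * boost, 1), n, n)
  wbase <- ifelse(same_mod, spec$w_in, spec$w_out) * boost

  ut <- upper.tri(prob)
  p_ut <- prob[ut]
  w_ut <- wbase[ut]
  m <- length(p_ut)

  lapply(seq_len(spec$n_subjects), function(s) {
    W <- with_seed(derive_seed(spec$seed, s), {
      on <- runif(m) < p_ut
      w <- numeric(m)
      w[on] <- w_ut[on] * exp(rnorm(sum(on), 0, spec$noise_sd))
      M <- matrix(0, n, n)
      M[ut] <- w
      M + t(M)
    })
    net <- weighted_network(W, labels = labels)
    list(network = net,
         labels = factor(labels, levels = c("H3", "H2", "SULCAL")),
         module = layout$module,
         hub_ids = layout$h3)
  })
}
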