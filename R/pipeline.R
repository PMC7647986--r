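#' Pipeline configuration
#'
#' Bundles every tunable setting of the end-to-end synthetic pipeline.
#' Defaults follow the reference analysis settings: 1000 patches,
#' modularity resolution 1, 1000 permutations, 400 dictionary atoms,
#' 4e4 fibers per subject. All randomness derives from `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of synthetic subjects.
#' @param n_patches Patches per subject.
#' @param n_junctions,n_ridges,mesh_resolution Folded-surface generator
#'   settings.
#' @param level Crest threshold (mm).
#' @param prune_mm Crest-line pruning threshold; `NULL` = 6 x median
#'   edge length.
#' @param snap_mm Endpoint snap distance (mm).
#' @param gamma Modularity resolution.
#' @param n_s_levels Number of decomposition levels.
#' @param n_perm Label permutations.
#' @param total_fibers Streamlines per subject.
#' @param hub_boost Multiplier applied to H3 patches when drawing fiber
#'   counts (planted hub structure).
#' @param k,lambda Dictionary size and sparsity penalty (functional
#'   stage).
#' @param run_functional Also run the dictionary-learning stage.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_subjects = 5, n_patches = 1000,
                            n_junctions = 5, n_ridges = 2,
                            mesh_resolution = 1, level = 0, prune_mm = NULL,
                            snap_mm = 2, gamma = 1, n_s_levels = 50,
                            n_perm = 1000, total_fibers = 40000,
                            hub_boost = 2, k = 400, lambda = 0.1,
                            run_functional = FALSE, seed = 1) {
  stopifnot(n_subjects >= 1, n_patches >= 2, n_perm >= 1, total_fibers >= 0)
  structure(
    list(out_dir = out_dir, n_subjects = n_subjects, n_patches = n_patches,
         n_junctions = n_junctions, n_ridges = n_ridges,
         mesh_resolution = mesh_resolution, level = level,
         prune_mm = prune_mm, snap_mm = snap_mm, gamma = gamma,
         n_s_levels = n_s_levels, n_perm = n_perm,
         total_fibers = total_fibers, hub_boost = hub_boost, k = k,
         lambda = lambda, run_functional = run_functional, seed = seed),
    class = "pipeline_config"
  )
}

# draw a symmetric fiber count matrix whose pair intensities favour
# H3-labelled patches and nearby patches (module-like locality)
plan_fiber_counts <- function(labels, seed_xy, total_fibers, hub_boost,
                              seed) {
  np <- nrow(seed_xy)
  mult <- ifelse(labels$class == "H3", 1 + hub_boost,
                 ifelse(labels$class == "H2", 1, 0.5))
  dd <- as.matrix(stats::dist(seed_xy))
  loc <- exp(-dd / (0.5 * max(dd)))
  inten <- outer(mult, mult) * loc
  diag(inten) <- diag(inten) / 4    # some within-patch loops
  ut <- which(upper.tri(inten, diag = TRUE))
  probs <- inten[ut] / sum(inten[ut])
  counts <- with_seed(seed, as.vector(stats::rmultinom(1, total_fibers,
                                                       probs)))
  M <- matrix(0, np, np)
  M[ut] <- counts
  M <- pmax(M, t(M))
  M
}

#' Run the full synthetic analysis pipeline
#'
#' Per subject: generate a folded surface, detect gyral hinges,
#' parcellate, label patches, synthesise streamlines with planted hub
#' structure, build the connectome, compute the six nodal metrics and
#' the decomposition ratio curves; then pool subjects for the H3 vs H2
#' group comparison and the curve-crossing permutation tests. Every
#' table is written as CSV under `out_dir` along with a `manifest.json`
#' recording the configuration, per-subject seeds and file checksums.
#' Outputs are byte-identical across re-runs with the same
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the pooled `metrics` tibble,
#'   `comparison` (group comparison), `curves` (cohort ratio curves),
#'   `crossing` (per-method permutation tests), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, s, expr) {
    tryCatch(expr, error = function(e) {
      stop_hinge("pipeline stage '", name, "' failed for subject ", s, ": ",
                 conditionMessage(e))
    })
  }

  metrics_all <- list()
  curves_score <- list()
  curves_strength <- list()
  crossing <- list()
  subj_seeds <- integer(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    seed_s <- derive_seed(config$seed, s)
    subj_seeds[s] <- seed_s
    surf <- stage("simulate-surface", s,
                  gen_folded_surface(n_ridges = config$n_ridges,
                                     n_junctions = config$n_junctions,
                                     mesh_resolution = config$mesh_resolution,
                                     seed = seed_s))
    mesh <- surf$mesh
    cg <- stage("detect-hinges", s,
                detect_hinges(mesh, level = config$level,
                              length_threshold = config$prune_mm))
    parc <- stage("parcellate", s,
                  equal_area_parcellate(mesh, config$n_patches,
                                        seed = seed_s))
    labels <- stage("label-patches", s,
                    label_patches(parc, cg$seg, cg, mesh))
    counts <- stage("plan-fibers", s,
                    plan_fiber_counts(labels,
                                      mesh$vertices[parc$seed_vertices, 1:2],
                                      config$total_fibers, config$hub_boost,
                                      derive_seed(seed_s, 1)))
    sl <- stage("simulate-streamlines", s,
                gen_streamlines(mesh, parc, counts, config$total_fibers,
                                seed = derive_seed(seed_s, 2)))
    pairs <- stage("assign-endpoints", s,
                   assign_endpoints(sl, mesh, parc, snap_mm = config$snap_mm))
    net <- stage("build-connectome", s,
                 build_connectivity(pairs, config$n_patches,
                                    labels = as.character(labels$class)))
    mt <- stage("metrics", s,
                compute_all_metrics(net, gamma = config$gamma,
                                    seed = derive_seed(seed_s, 3),
                                    subject_id = s))
    lv <- default_s_levels(net, config$n_s_levels)
    curves_score[[s]] <- stage("decompose", s,
                               ratio_curves(net, s_levels = lv,
                                            method = "s_core"))
    curves_strength[[s]] <- ratio_curves(net, s_levels = lv,
                                         method = "strength")
    crossing[[s]] <- list(
      s_core = crossing_permutation_test(net, s_levels = lv,
                                         method = "s_core",
                                         n_perm = config$n_perm,
                                         seed = derive_seed(seed_s, 4)),
      strength = crossing_permutation_test(net, s_levels = lv,
                                           method = "strength",
                                           n_perm = config$n_perm,
                                           seed = derive_seed(seed_s, 5))
    )
    metrics_all[[s]] <- mt
  }
  metrics <- bind_rows(metrics_all)
  comparison <- compare_metrics(metrics, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 999))
  cohort_sc <- cohort_ratio_curves(curves_score)
  cohort_st <- cohort_ratio_curves(curves_strength)

  functional_cmp <- NULL
  if (isTRUE(config$run_functional)) {
    sig <- gen_signal_matrix(t = 80, n = 4 * config$n_patches, k = config$k,
                             sparsity = 2, noise_sd = 0.05,
                             seed = derive_seed(config$seed, 1001))
    model <- learn_dictionary(sig$X, k = config$k, lambda = config$lambda,
                              seed = derive_seed(config$seed, 1002),
                              n_iters = 5)
    cls <- rep(c("H3", "H2", "other", "other"), config$n_patches)
    functional_cmp <- compare_involvement(involvement_counts(model), cls)
    write.csv(functional_cmp, file.path(config$out_dir, "functional.csv"),
              row.names = FALSE)
  }

  write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
            row.names = FALSE)
  write.csv(cohort_sc, file.path(config$out_dir, "curves_score.csv"),
            row.names = FALSE)
  write.csv(cohort_st, file.path(config$out_dir, "curves_strength.csv"),
            row.names = FALSE)
  crossing_tbl <- bind_rows(lapply(seq_along(crossing), function(s) {
    tibble(subject = s,
           method = c("s_core", "strength"),
           observed = c(crossing[[s]]$s_core$observed_event,
                        crossing[[s]]$strength$observed_event),
           p_value = c(crossing[[s]]$s_core$p_value,
                       crossing[[s]]$strength$p_value))
  }))
  write.csv(crossing_tbl, file.path(config$out_dir, "crossing.csv"),
            row.names = FALSE)

  files <- c("metrics.csv", "comparison.csv", "curves_score.csv",
             "curves_strength.csv", "crossing.csv",
             if (!is.null(functional_cmp)) "functional.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("hingenet")),
    config = config[setdiff(names(config), "out_dir")],
    subject_seeds = subj_seeds,
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, comparison = comparison,
                 curves = list(s_core = cohort_sc, strength = cohort_st),
                 crossing = crossing_tbl, functional = functional_cmp,
                 manifest = manifest))
}
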