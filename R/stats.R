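#' Within-subject z-score normalisation of a metric table
#'
#' Per subject and per metric, transforms values to `(x - mean) / sd`
#' over all patches of the subject (sulcal patches included, so gyral
#' class means remain interpretable). The transform is idempotent.
#'
#' @param table Metric tibble with a `subject` column (see
#'   [compute_all_metrics()]).
#' @param metrics Character vector of metric column names.
#' @return The table with the metric columns standardised.
#' @export
zscore_within_subject <- function(table, metrics = hinge_metric_names()) {
  for (m in metrics) {
    if (!m %in% names(table)) stop_hinge("missing metric column: ", m)
  }
  split_idx <- split(seq_len(nrow(table)), table$subject)
  for (idx in split_idx) {
    if (length(idx) < 2L) stop_hinge("need >= 2 nodes per subject to z-score")
    for (m in metrics) {
      x <- table[[m]][idx]
      s <- sd(x)
      if (!is.finite(s) || s == 0) {
        stop_hinge("zero variance in metric '", m, "': cannot z-score")
      }
      table[[m]][idx] <- (x - mean(x)) / s
    }
  }
  table
}

#' Two-sample t-test (Welch by default)
#'
#' Thin wrapper returning a one-row tibble. `var_equal = TRUE` gives the
#' pooled-variance test. Two identical degenerate groups return t = 0,
#' p = 1 rather than an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance test instead of Welch.
#' @return Tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
ttest_two_sample <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_hinge("each group needs at least 2 values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2,
                  p = if (same) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Label-shuffling permutation test for an H3 vs H2 metric contrast
#'
#' The statistic is the absolute difference between the H3 and H2 group
#' means (the directed difference taken in whichever direction the
#' observed data favours). The null distribution comes from `n_perm`
#' class-size-preserving label shuffles — within each subject when a
#' `subject` vector is given, with the statistic evaluated on the pooled
#' groups. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param values Numeric per-patch metric values.
#' @param labels Class labels; exactly the H3 and H2 entries enter the
#'   test (others are ignored but keep their positions in the shuffle
#'   blocks fixed — shuffles permute labels over the gyral patches).
#' @param n_perm Number of permutations (>= 1). Default 1000.
#' @param seed Integer seed.
#' @param subject Optional per-value subject ids for within-subject
#'   shuffling.
#' @return An object of class `hinge_perm_test`: `p_value`, `observed`
#'   (absolute mean difference), `direction` (`"h3>h2"` or `"h2>h3"`),
#'   `mean_h3`, `mean_h2`, `n_perm`.
#' @export
label_permutation_test <- function(values, labels, n_perm = 1000, seed = 1,
                                   subject = NULL) {
  stopifnot(n_perm >= 1)
  labels <- as.character(labels)
  keep <- labels %in% c("H3", "H2")
  values <- values[keep]
  labels <- labels[keep]
  if (!is.null(subject)) subject <- subject[keep]
  if (!any(labels == "H3") || !any(labels == "H2")) {
    stop_hinge("both H3 and H2 labels are required")
  }
  stat <- function(lab) {
    abs(mean(values[lab == "H3"]) - mean(values[lab == "H2"]))
  }
  observed <- stat(labels)
  blocks <- if (is.null(subject)) list(seq_along(values)) else
    split(seq_along(values), subject)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      lab <- labels
      for (idx in blocks) lab[idx] <- lab[idx][sample.int(length(idx))]
      stat(lab)
    }, numeric(1))
  })
  structure(
    list(p_value = (1 + sum(null_stats >= observed)) / (1 + n_perm),
         observed = observed,
         direction = if (mean(values[labels == "H3"]) >=
                         mean(values[labels == "H2"])) "h3>h2" else "h2>h3",
         mean_h3 = mean(values[labels == "H3"]),
         mean_h2 = mean(values[labels == "H2"]),
         n_perm = n_perm),
    class = "hinge_perm_test"
  )
}

#' @export
print.hinge_perm_test <- function(x, ...) {
  cat(sprintf("<hinge_perm_test> p = %.4g (%d permutations)\n",
              x$p_value, x$n_perm))
  invisible(x)
}

#' @method tidy hinge_perm_test
#' @export
tidy.hinge_perm_test <- function(x, ...) {
  tibble(
    p_value = x$p_value, n_perm = x$n_perm,
    observed = x[["observed"]] %||% as.numeric(x[["observed_event"]]),
    direction = x[["direction"]] %||% NA_character_,
    method = x[["method"]] %||% "label_permutation"
  )
}

#' Group comparison table for a cohort of metric tables
#'
#' Builds a Table-1-shaped comparison: per metric, the H3 and H2 means
#' and sds of the within-subject z-scored values pooled over subjects,
#' a two-sample t-test, and a label-shuffling permutation test.
#'
#' @param table Metric tibble (several subjects stacked), with `subject`,
#'   `class` and metric columns.
#' @param metrics Metric columns to compare.
#' @param n_perm Permutations per metric (default 1000).
#' @param seed Integer seed.
#' @param zscore Apply [zscore_within_subject()] first (default TRUE).
#' @return A tibble of class `group_comparison`: one row per metric with
#'   `mean_h3`, `sd_h3`, `mean_h2`, `sd_h2`, `t`, `p_ttest`,
#'   `p_permutation`, `n_perm`, `direction`.
#' @export
compare_metrics <- function(table, metrics = hinge_metric_names(),
                            n_perm = 1000, seed = 1, zscore = TRUE) {
  if (zscore) table <- zscore_within_subject(table, metrics)
  rows <- lapply(seq_along(metrics), function(k) {
    m <- metrics[k]
    x <- table[[m]][table$class == "H3"]
    y <- table[[m]][table$class == "H2"]
    if (length(x) < 2L || length(y) < 2L) {
      stop_hinge("class with fewer than 2 patches for metric '", m, "'")
    }
    tt <- ttest_two_sample(x, y)
    pt <- label_permutation_test(table[[m]], table$class, n_perm = n_perm,
                                 seed = derive_seed(seed, k),
                                 subject = table$subject)
    tibble(
      metric = m,
      mean_h3 = mean(x), sd_h3 = sd(x),
      mean_h2 = mean(y), sd_h2 = sd(y),
      t = tt$t, p_ttest = tt$p,
      p_permutation = pt$p_value, n_perm = n_perm,
      direction = pt$direction
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Cross-species comparison of hinge metrics
#'
#' Within each species the (within-subject normalised) metric values are
#' z-scored across subjects, then every species pair is compared per
#' metric and per convolution class with two-sample t-tests.
#'
#' @param cohorts Named list (>= 2 species) of stacked metric tibbles,
#'   each with >= 2 subjects and both H3 and H2 patches.
#' @param metrics Metric columns to compare.
#' @param zscore_within Apply [zscore_within_subject()] per species
#'   first (default TRUE).
#' @return Tibble: `species_a`, `species_b`, `class`, `metric`,
#'   per-species means and sds, `t`, `p`.
#' @export
cross_species_compare <- function(cohorts, metrics = hinge_metric_names(),
                                  zscore_within = TRUE) {
  if (length(cohorts) < 2L || is.null(names(cohorts))) {
    stop_hinge("need a named list of >= 2 species cohorts")
  }
  cohorts <- lapply(names(cohorts), function(sp) {
    tb <- cohorts[[sp]]
    if (length(unique(tb$subject)) < 2L) {
      stop_hinge("species '", sp, "' needs >= 2 subjects")
    }
    for (cl in c("H3", "H2")) {
      if (!any(tb$class == cl)) {
        stop_hinge("species '", sp, "' is missing class ", cl)
      }
    }
    if (zscore_within) tb <- zscore_within_subject(tb, metrics)
    for (m in metrics) {  # second round: z across subjects within species
      tb[[m]] <- (tb[[m]] - mean(tb[[m]])) / sd(tb[[m]])
    }
    tb$species <- sp
    tb
  })
  names(cohorts) <- vapply(cohorts, function(tb) tb$species[1], character(1))
  pairs <- utils::combn(names(cohorts), 2)
  rows <- list()
  for (pp in seq_len(ncol(pairs))) {
    a <- pairs[1, pp]
    b <- pairs[2, pp]
    for (cl in c("H3", "H2")) {
      for (m in metrics) {
        x <- cohorts[[a]][[m]][cohorts[[a]]$class == cl]
        y <- cohorts[[b]][[m]][cohorts[[b]]$class == cl]
        tt <- ttest_two_sample(x, y)
        rows[[length(rows) + 1L]] <- tibble(
          species_a = a, species_b = b, class = cl, metric = m,
          mean_a = mean(x), sd_a = sd(x), mean_b = mean(y), sd_b = sd(y),
          t = tt$t, p = tt$p
        )
      }
    }
  }
  bind_rows(rows)
}
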