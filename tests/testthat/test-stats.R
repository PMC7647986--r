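mk_table <- function(n_subj, n_nodes, shift_h3 = 0, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_subj), function(s) {
      cls <- sample(rep(c("H3", "H2", "SULCAL"),
                        length.out = n_nodes))
      tibble::tibble(
        subject = s, node = seq_len(n_nodes), class = cls,
        degree = stats::rnorm(n_nodes) + shift_h3 * (cls == "H3"),
        strength = stats::rnorm(n_nodes) + shift_h3 * (cls == "H3"),
        betweenness = stats::rnorm(n_nodes),
        efficiency = stats::rnorm(n_nodes),
        clustering = stats::runif(n_nodes),
        participation = stats::runif(n_nodes)
      )
    }))
  })
}

test_that("within-subject z-scoring normalises exactly and is idempotent", {
  tb <- mk_table(3, 50, seed = 2)
  z <- zscore_within_subject(tb)
  for (s in 1:3) {
    for (m in c("degree", "clustering")) {
      x <- z[[m]][z$subject == s]
      expect_equal(mean(x), 0, tolerance = 1e-9)
      expect_equal(sd(x), 1, tolerance = 1e-9)
    }
  }
  expect_equal(zscore_within_subject(z), z, tolerance = 1e-9)

  # hand z-score of a constant-plus-outlier vector
  tb1 <- tibble::tibble(subject = 1, degree = c(2, 2, 2, 10))
  z1 <- zscore_within_subject(tb1, metrics = "degree")
  expect_equal(z1$degree, (c(2, 2, 2, 10) - 4) / 4)

  tbc <- tibble::tibble(subject = 1, degree = rep(3, 5))
  expect_error(zscore_within_subject(tbc, metrics = "degree"),
               "zero variance.*degree")
  expect_error(zscore_within_subject(tb, metrics = "no_such"),
               "missing metric")
})

test_that("two-sample t-test wrapper handles edges and is calibrated", {
  expect_equal(ttest_two_sample(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(ttest_two_sample(c(1, 1, 1), c(1, 1, 1))$p, 1)

  jit <- c(1e-6, -1e-6, 2e-6, -2e-6)
  res <- ttest_two_sample(c(0, 0, 0, 0) + jit, c(1, 1, 1, 1) + jit)
  expect_lt(res$p, 1e-3)
  expect_error(ttest_two_sample(1, c(1, 2)), "at least 2")

  # type-I error at alpha = 0.05 over 1000 null replicates
  rej <- withr::with_seed(42, {
    mean(vapply(seq_len(1000), function(i) {
      ttest_two_sample(stats::rnorm(20), stats::rnorm(20))$p < 0.05
    }, logical(1)))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("label permutation test: extremes, invariance, uniform null", {
  # complete separation: smallest attainable p
  v <- c(rep(10, 8), rep(0, 20))
  lab <- c(rep("H3", 8), rep("H2", 20))
  pt <- label_permutation_test(v, lab, n_perm = 500, seed = 1)
  expect_equal(pt$p_value, 1 / 501)
  expect_equal(pt$direction, "h3>h2")

  # invariance under affine transforms of the values
  v2 <- withr::with_seed(3, stats::rnorm(40))
  lab2 <- rep(c("H3", "H2"), 20)
  p_raw <- label_permutation_test(v2, lab2, n_perm = 200, seed = 9)$p_value
  p_aff <- label_permutation_test(5 * v2 + 2, lab2, n_perm = 200,
                                  seed = 9)$p_value
  expect_equal(p_raw, p_aff)

  # approximately uniform null p-values (KS at alpha = 0.01)
  ps <- withr::with_seed(11, {
    vapply(seq_len(200), function(i) {
      label_permutation_test(stats::rnorm(60),
                             sample(rep(c("H3", "H2"), c(20, 40))),
                             n_perm = 99, seed = i)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(label_permutation_test(v, rep("H2", 28)), "H3")
  expect_error(label_permutation_test(v, lab, n_perm = 0), "n_perm")
})

test_that("compare_metrics pools subjects into a Table-1 shape", {
  tb <- mk_table(4, 60, shift_h3 = 1.5, seed = 5)
  cmp <- compare_metrics(tb, n_perm = 200, seed = 3)
  expect_equal(cmp$metric, hinge_metric_names())
  expect_equal(cmp$direction[1], "h3>h2")
  expect_lt(cmp$p_permutation[1], 0.01)   # planted degree shift
  expect_lt(cmp$p_ttest[2], 0.001)        # planted strength shift
  # null metrics stay unremarkable
  expect_gt(min(cmp$p_permutation[3:6]), 0.01)
})

test_that("cross-species comparison flags only the planted contrast", {
  mk_species <- function(shift_h3, seed) mk_table(3, 60, shift_h3, seed)
  cohorts <- list(human = mk_species(1.5, 1),
                  chimp = mk_species(0, 2),
                  macaque = mk_species(0, 3))
  out <- cross_species_compare(cohorts, metrics = c("degree", "strength"))
  # full shape: 3 pairs x 2 classes x 2 metrics
  expect_equal(nrow(out), 12)
  expect_setequal(unique(out$class), c("H3", "H2"))
  hm <- out[out$species_a == "human" & out$class == "H3" &
              out$metric == "degree", ]
  expect_true(all(hm$p < 0.01))         # planted H3 shift in humans
  cm <- out[out$species_a == "chimp" & out$species_b == "macaque", ]
  expect_gt(min(cm$p), 0.05)            # exchangeable species pair

  expect_error(cross_species_compare(list(a = mk_species(0, 1))), "2 species")
  one_subj <- mk_table(1, 40, seed = 4)
  expect_error(cross_species_compare(list(a = one_subj, b = one_subj)),
               "2 subjects")
})
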