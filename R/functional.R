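# Coordinate-descent lasso coder for a fixed dictionary.
# Solves, per column x of X:  min_a 0.5 ||x - D a||^2 + lambda ||a||_1.
# G = t(D) D and t(D) X are precomputed; coordinate updates are exact
# soft-thresholding steps, so converged coefficients contain exact zeros.
sparse_code <- function(D, X, lambda, max_sweeps = 100, tol = 1e-8) {
  G <- crossprod(D)
  DtX <- crossprod(D, X)
  k <- ncol(D)
  n <- ncol(X)
  gd <- diag(G)
  gd[gd == 0] <- 1
  A <- matrix(0, k, n)
  for (i in seq_len(n)) {
    a <- A[, i]
    ga <- as.vector(G %*% a)
    for (sw in seq_len(max_sweeps)) {
      delta <- 0
      for (j in seq_len(k)) {
        r <- DtX[j, i] - ga[j] + gd[j] * a[j]
        new <- sign(r) * max(0, abs(r) - lambda) / gd[j]
        if (new != a[j]) {
          ga <- ga + G[, j] * (new - a[j])
          delta <- max(delta, abs(new - a[j]))
          a[j] <- new
        }
      }
      if (delta < tol) break
    }
    A[, i] <- a
  }
  A
}

#' Online dictionary learning with sparse coding
#'
#' Factorises a signal matrix `X` (time points x signals) into an
#' over-complete dictionary `D` (t x k) and sparse coefficients `alpha`
#' (k x n) by mini-batch alternation: each batch is sparse-coded against
#' the current dictionary (l1-penalised least squares via coordinate
#' descent), sufficient statistics are accumulated, and the dictionary
#' atoms are updated by block coordinate descent with unit-ball
#' projection. Columns are centred and variance-normalised before
#' fitting by default. Deterministic given the seed (initial atoms and
#' batch order).
#'
#' @param X Numeric t x n matrix of signals (columns).
#' @param k Number of dictionary atoms (>= 1).
#' @param lambda l1 sparsity penalty (default 0.1 on unit-variance
#'   columns).
#' @param seed Integer seed.
#' @param n_iters Number of epochs over the data (default 20).
#' @param batch_size Mini-batch size (default 256).
#' @param normalize Centre and variance-normalise columns first.
#' @return An object of class `sparse_code_model`: `D`, `alpha`, `k`,
#'   `lambda`, `zero_tol`, `involvement` (per-column l0 counts),
#'   `recon_error` (relative Frobenius error per epoch).
#' @export
learn_dictionary <- function(X, k, lambda = 0.1, seed = 1, n_iters = 20,
                             batch_size = 256, normalize = TRUE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_hinge("X must be finite")
  t_ <- nrow(X)
  n <- ncol(X)
  stopifnot(k >= 1, n_iters >= 1, batch_size >= 1)
  if (k > t_ * n) stop_hinge("infeasible: k exceeds the number of entries")
  if (normalize) {
    X <- sweep(X, 2, colMeans(X))
    sds <- sqrt(colMeans(X^2))
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  xnorm <- sqrt(sum(X^2))
  if (xnorm == 0) stop_hinge("X is identically zero")

  with_seed(seed, {
    # greedy incoherent init: start from a seeded column, then keep
    # adding the column least correlated with the atoms chosen so far
    Xu <- sweep(X, 2, pmax(sqrt(colSums(X^2)), 1e-12), "/")
    init_idx <- integer(min(k, n))
    init_idx[1] <- sample.int(n, 1)
    if (length(init_idx) > 1) {
      maxcor <- abs(as.vector(crossprod(Xu, Xu[, init_idx[1]])))
      for (q in 2:length(init_idx)) {
        init_idx[q] <- which.min(maxcor)
        maxcor <- pmax(maxcor,
                       abs(as.vector(crossprod(Xu, Xu[, init_idx[q]]))))
      }
    }
    if (k > n) init_idx <- c(init_idx, sample.int(n, k - n, replace = TRUE))
    D <- X[, init_idx, drop = FALSE] +
      matrix(rnorm(t_ * k, 0, 1e-3), t_, k)
    nrm <- sqrt(colSums(D^2))
    nrm[nrm == 0] <- 1
    D <- sweep(D, 2, nrm, "/")

    A <- matrix(0, k, k)
    B <- matrix(0, t_, k)
    err <- numeric(n_iters)
    for (ep in seq_len(n_iters)) {
      ord <- sample.int(n)
      for (st in seq(1L, n, by = batch_size)) {
        cols <- ord[st:min(st + batch_size - 1L, n)]
        Xb <- X[, cols, drop = FALSE]
        Ab <- sparse_code(D, Xb, lambda)
        A <- A + tcrossprod(Ab)
        B <- B + tcrossprod(Xb, Ab)
        for (j in seq_len(k)) {
          if (A[j, j] > 1e-10) {
            u <- (B[, j] - D %*% A[, j]) / A[j, j] + D[, j]
            D[, j] <- u / max(1, sqrt(sum(u^2)))
          }
        }
      }
      alpha_ep <- sparse_code(D, X, lambda)
      resid <- X - D %*% alpha_ep
      err[ep] <- sqrt(sum(resid^2)) / xnorm
      if (ep < n_iters) {
        # revive unused atoms with the worst-reconstructed column
        dead <- which(diag(A) <= 1e-10)
        if (length(dead) > 0) {
          worst <- order(-colSums(resid^2))
          for (q in seq_along(dead)) {
            v <- resid[, worst[min(q, length(worst))]]
            if (sqrt(sum(v^2)) > 1e-8) D[, dead[q]] <- v / sqrt(sum(v^2))
          }
        }
      }
    }
    alpha <- sparse_code(D, X, lambda)
    zero_tol <- 1e-8
    structure(
      list(D = D, alpha = alpha, k = k, lambda = lambda,
           zero_tol = zero_tol,
           involvement = as.integer(colSums(abs(alpha) > zero_tol)),
           recon_error = err),
      class = "sparse_code_model"
    )
  })
}

#' @export
print.sparse_code_model <- function(x, ...) {
  cat(sprintf(
    "<sparse_code_model> k = %d atoms, lambda = %g, rel. error %.3f\n",
    x$k, x$lambda, utils::tail(x$recon_error, 1)))
  invisible(x)
}

#' @method glance sparse_code_model
#' @export
glance.sparse_code_model <- function(x, ...) {
  tibble(k = x$k, lambda = x$lambda,
         recon_error = utils::tail(x$recon_error, 1),
         mean_involvement = mean(x$involvement),
         median_involvement = median(x$involvement))
}

#' @method tidy sparse_code_model
#' @export
tidy.sparse_code_model <- function(x, ...) {
  tibble(column = seq_along(x$involvement), involvement = x$involvement)
}

#' Functional involvement counts
#'
#' Number of nonzero coefficients per signal column, i.e. how many
#' learned functional networks each vertex participates in. Entries with
#' magnitude above the model's `zero_tol` count as nonzero.
#'
#' @param model A `sparse_code_model`.
#' @return Integer vector of per-column counts.
#' @export
involvement_counts <- function(model) {
  stopifnot(inherits(model, "sparse_code_model"))
  as.integer(colSums(abs(model$alpha) > model$zero_tol))
}

#' Compare functional involvement between H3 and H2 vertices
#'
#' Mean (+/- sd) involvement per class and a two-sample t-test of the
#' null hypothesis that 3-hinge and 2-hinge vertices participate in the
#' same number of functional networks.
#'
#' @param counts Per-vertex involvement counts.
#' @param vertex_classes Per-vertex class labels (H3/H2/other).
#' @return One-row `group_comparison` tibble.
#' @export
compare_involvement <- function(counts, vertex_classes) {
  cls <- as.character(vertex_classes)
  x <- counts[cls == "H3"]
  y <- counts[cls == "H2"]
  if (length(x) < 2L || length(y) < 2L) {
    stop_hinge("both H3 and H2 classes need >= 2 vertices")
  }
  tt <- ttest_two_sample(as.numeric(x), as.numeric(y))
  out <- tibble(
    metric = "involvement",
    mean_h3 = mean(x), sd_h3 = sd(x),
    mean_h2 = mean(y), sd_h2 = sd(y),
    t = tt$t, p_ttest = tt$p,
    direction = if (mean(x) >= mean(y)) "h3>h2" else "h2>h3"
  )
  class(out) <- c("group_comparison", class(out))
  out
}
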