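#' Generate a sparse-coded signal matrix with known ground truth
#'
#' Draws an over-complete dictionary of `k` smooth random time series and
#' a sparse coefficient matrix in which every column combines exactly
#' `sparsity` dictionary atoms, then returns `X = D alpha + noise`. The
#' ground truth records the true dictionary, coefficients and per-column
#' support counts, giving an analytic reference for dictionary-learning
#' recovery experiments.
#'
#' @param t Number of time points.
#' @param n Number of signals (columns).
#' @param k Number of dictionary components (atoms).
#' @param sparsity Nonzero atoms per column (<= k).
#' @param noise_sd Gaussian noise sd added to each entry.
#' @param seed Integer seed.
#' @return List with `X` (t x n matrix) and `ground_truth` (list:
#'   `true_dictionary` t x k, `true_coefficients` k x n,
#'   `support_counts` length-n integer).
#' @export
gen_signal_matrix <- function(t, n, k, sparsity = 1, noise_sd = 0, seed = 1) {
  stopifnot(t >= 2, n >= 1, k >= 1, noise_sd >= 0)
  if (sparsity < 1 || sparsity > k) stop_hinge("sparsity must be in [1, k]")
  with_seed(seed, {
    # atoms: lightly smoothed white noise, centred and scaled to unit
    # norm -- smooth enough to look like slow haemodynamic time courses,
    # incoherent enough that sparse supports are identifiable
    D <- apply(matrix(rnorm(t * k), t, k), 2, function(z) {
      as.vector(stats::filter(z, rep(1 / 3, 3), sides = 2, circular = TRUE))
    })
    D <- sweep(D, 2, colMeans(D))
    nrmD <- sqrt(colSums(D^2))
    nrmD[nrmD == 0] <- 1
    D <- sweep(D, 2, nrmD, "/")
    alpha <- matrix(0, k, n)
    for (i in seq_len(n)) {
      sup <- sample.int(k, sparsity)
      alpha[sup, i] <- runif(sparsity, 1, 2) * sample(c(-1, 1), sparsity,
                                                      replace = TRUE)
    }
    X <- D %*% alpha
    if (noise_sd > 0) X <- X + matrix(rnorm(t * n, 0, noise_sd), t, n)
    list(
      X = X,
      ground_truth = list(
        true_dictionary = D,
        true_coefficients = alpha,
        support_counts = as.integer(colSums(alpha != 0))
      )
    )
  })
}
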