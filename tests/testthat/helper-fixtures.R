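# Shared fixture builders. All fixtures are generated in code at test time.

# small default generator spec used across tests
small_spec <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_cells_per_type = 30, n_types = 3,
               marker_frac = 0.05, marker_fold = 8, base_mean = 5,
               dispersion = 0.2, libsize_sigma = 0.2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(single_cell_spec, args)
}

# a well-conditioned genes x K signature with one block of pure markers per
# type and equal column totals, so simplex-normalized estimates are unbiased
make_separable_C <- function(M = 120, K = 4, n_markers = 8, seed = 11) {
  stopifnot(M > K * n_markers)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    C <- matrix(runif(M * K, 1, 3), M, K)
    for (k in seq_len(K)) {
      rows <- ((k - 1) * n_markers + 1):(k * n_markers)
      C[rows, ] <- 0 # pure markers: zero off-type expression
      C[rows, k] <- 25 + runif(n_markers, 0, 5)
    }
    C <- sweep(C, 2, colSums(C), "/") * 1000 # equal column totals
    rownames(C) <- sprintf("gene_%05d", seq_len(M))
    colnames(C) <- sprintf("type_%d", seq_len(K))
    C
  })
}

# noiseless mixture G = C %*% P as a pseudo_bulk with known truth
make_noiseless_bulk <- function(C, n = 20, p = rep(1, ncol(C)), seed = 5) {
  P <- sample_proportions(dirichlet_spec(p, n, seed = seed,
                                         type_names = colnames(C)))
  pseudo_bulk(C %*% P$values, P)
}

# a labelled reference whose type means are exactly C: per type, two pairs of
# cells C[,k] +/- d with zero-sum perturbations, so all cell totals are equal
# and the equal-total normalization in build_signature is the identity
make_exact_reference <- function(C, jitter = 0.02, seed = 21) {
  M <- nrow(C)
  K <- ncol(C)
  set.seed(seed)
  cells <- list()
  labels <- character(0)
  for (k in seq_len(K)) {
    for (r in 1:2) {
      # multiplicative zero-sum jitter: d = e * C[,k] with sum(d) = 0 and
      # |e| < 1, so C[,k] +/- d stays non-negative, totals stay equal, and
      # the pairwise mean is exactly C[,k]
      e <- runif(M, -10 * jitter, 10 * jitter)
      e <- e - sum(e * C[, k]) / sum(C[, k])
      e <- pmax(pmin(e, 0.9), -0.9)
      d <- e * C[, k]
      d <- d - sum(d) / M # tiny re-centering after clipping, spread evenly
      cells <- c(cells, list(C[, k] + d), list(C[, k] - d))
      labels <- c(labels, colnames(C)[k], colnames(C)[k])
    }
  }
  counts <- do.call(cbind, cells)
  counts <- pmax(counts, 0)
  new_sc <- deconvbench:::new_single_cell_dataset
  new_sc(counts, rownames(C), labels, colnames(C))
}

expect_column_stochastic <- function(P, tol = 1e-8) {
  vals <- if (inherits(P, "proportion_matrix")) P$values else P
  expect_true(all(vals >= -tol))
  expect_equal(unname(colSums(vals)), rep(1, ncol(vals)), tolerance = tol)
}
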