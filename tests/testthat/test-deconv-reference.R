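test_that("build_signature recovers planted markers and type means", {
  sc <- generate_single_cell_dataset(small_spec(
    seed = 1, n_cells_per_type = 60, dispersion = 0.05, marker_fold = 10))
  sig <- build_signature(sc, n_markers_per_type = 15)
  planted <- unlist(sc$marker_sets)
  expect_true(all(planted %in% sig$gene_ids))

  # column k equals the per-type mean of the equal-total-normalized cells
  norm <- sweep(sc$counts, 2, colSums(sc$counts) / mean(colSums(sc$counts)),
                "/")
  for (k in seq_along(sc$type_names)) {
    mu <- rowMeans(norm[, sc$cell_types == sc$type_names[k], drop = FALSE])
    expect_equal(unname(sig$values[, k]),
                 unname(mu[match(sig$gene_ids, sc$gene_ids)]),
                 tolerance = 1e-9)
  }
})

test_that("build_signature degenerates deterministically on identical types", {
  # identical type means: t-statistics ~ 0, tie-break by gene order
  C <- make_separable_C(M = 60, K = 2, n_markers = 5)
  counts <- cbind(C[, 1] + 1, C[, 1] - 1, C[, 1] + 2, C[, 1] - 2)
  counts <- pmax(counts, 0)
  rownames(counts) <- rownames(C)
  sc <- deconvbench:::new_single_cell_dataset(
    counts, rownames(C), c("a", "a", "b", "b"), c("a", "b"))
  s1 <- build_signature(sc, 10)
  s2 <- build_signature(sc, 10)
  expect_identical(s1$gene_ids, s2$gene_ids)
  expect_error(build_signature(sc, 1e6), "n_markers_per_type")
})

test_that("NNLS exactly recovers noiseless separable mixtures", {
  C <- make_separable_C(M = 120, K = 4)
  sig <- signature_matrix(C)
  bulk <- make_noiseless_bulk(C, n = 20, p = c(5.4, 3.5, 1.1, 0.5))
  fit <- nnls_deconv(bulk, sig)
  expect_lt(max(abs(coef(fit) - bulk$truth$values)), 1e-6)
  expect_column_stochastic(fit$proportions)

  # pure column: a sample equal to column k of C recovers e_k
  pure <- pseudo_bulk(C, proportion_matrix(diag(4), colnames(C)))
  fp <- nnls_deconv(pure, sig)
  expect_equal(unname(coef(fp)), diag(4), tolerance = 1e-8)

  # all-zero sample is a contract violation, not 0/0
  z <- bulk
  z$expression[, 3] <- 0
  expect_error(nnls_deconv(z, sig), "degenerate sample 3")
})

test_that("solvers are invariant to positive rescaling of the bulk", {
  C <- make_separable_C(M = 120, K = 4)
  sig <- signature_matrix(C)
  bulk <- make_noiseless_bulk(C, n = 12, seed = 8)
  scaled <- bulk
  scaled$expression <- bulk$expression * 137.5
  expect_equal(coef(nnls_deconv(bulk, sig)),
               coef(nnls_deconv(scaled, sig)), tolerance = 1e-8)
  expect_equal(coef(nusvr_deconv(bulk, sig)),
               coef(nusvr_deconv(scaled, sig)), tolerance = 1e-6)
  ref <- make_exact_reference(C)
  expect_equal(coef(wnnls_deconv(bulk, ref, n_markers_per_type = 20)),
               coef(wnnls_deconv(scaled, ref, n_markers_per_type = 20)),
               tolerance = 1e-6)
})

test_that("w-NNLS reduces to NNLS under constant weights and recovers exactly", {
  # rows of C are permutations of one value set: between-type variance is
  # constant across genes; the reference has equal within-type variances;
  # noiseless data leave residuals at zero, so all weights are equal
  vals <- c(2, 5, 9, 14)
  K <- 4
  M <- 48
  C <- t(vapply(seq_len(M), function(g) vals[((g + seq_len(K)) %% K) + 1],
                numeric(K)))
  rownames(C) <- sprintf("gene_%05d", seq_len(M))
  colnames(C) <- sprintf("type_%d", seq_len(K))
  ref <- make_exact_reference(C, jitter = 0.01)
  bulk <- make_noiseless_bulk(C, n = 15, seed = 4)

  w_fit <- wnnls_deconv(bulk, ref, n_markers_per_type = M / K)
  sig <- build_signature(ref, n_markers_per_type = M / K)
  n_fit <- nnls_deconv(bulk, sig)
  expect_lt(max(abs(coef(w_fit) - coef(n_fit))), 1e-6)
  expect_lt(max(abs(coef(w_fit) - bulk$truth$values)), 1e-6)
})

test_that("w-NNLS beats NNLS under gene-concentrated heteroscedastic noise", {
  # paired simulation: noise lives on half the genes, and the reference's
  # within-type variance exposes exactly those genes; the weighted solver
  # must win on mean RMSD in most replicates (sign test)
  C <- make_separable_C(M = 120, K = 4, seed = 2)
  noisy_rows <- seq_len(60)
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    P <- sample_proportions(dirichlet_spec(c(2, 2, 2, 2), 50,
                                           seed = 200 + r,
                                           type_names = colnames(C)))
    G <- C %*% P$values
    G[noisy_rows, ] <- G[noisy_rows, ] *
      exp(matrix(rnorm(60 * 50, 0, 1), 60, 50))
    bulk <- pseudo_bulk(G, P)

    # reference with 40 cells per type: type means stay stable, but the
    # within-type variance exposes exactly the noisy genes
    set.seed(300 + r)
    counts <- do.call(cbind, lapply(1:4, function(k) {
      m <- matrix(C[, k], 120, 40)
      m[noisy_rows, ] <- m[noisy_rows, ] *
        exp(matrix(rnorm(60 * 40, 0, 1), 60, 40))
      m[-noisy_rows, ] <- m[-noisy_rows, ] *
        exp(matrix(rnorm(60 * 40, 0, 0.01), 60, 40))
      m
    }))
    ref <- deconvbench:::new_single_cell_dataset(
      counts, rownames(C), rep(colnames(C), each = 40), colnames(C))

    sig <- build_signature(ref, n_markers_per_type = 30)
    r_w <- rmsd(bulk$truth,
                suppressWarnings(wnnls_deconv(bulk, ref,
                                              n_markers_per_type = 30)))
    r_n <- rmsd(bulk$truth, nnls_deconv(bulk, sig))
    wins <- wins + (r_w < r_n)
  }
  expect_gte(wins, 15) # sign test: P(X >= 15 | p = 0.5, n = 20) < 0.021
})

test_that("nu-SVR recovers noiseless mixtures and tolerates duplicate rows", {
  C <- make_separable_C(M = 120, K = 4)
  sig <- signature_matrix(C)
  bulk <- make_noiseless_bulk(C, n = 20, p = c(5.4, 3.5, 1.1, 0.5),
                              seed = 9)
  fit <- nusvr_deconv(bulk, sig)
  expect_column_stochastic(fit$proportions)
  expect_gt(pearson_r(bulk$truth, fit), 0.99)

  # duplicating gene rows (signature + observation) leaves estimates
  # unchanged after de-duplication
  dup_rows <- c(seq_len(120), 1:30)
  C2 <- C[dup_rows, ]
  rownames(C2) <- sprintf("gene_%05d", seq_len(150))
  bulk2 <- pseudo_bulk(bulk$expression[dup_rows, ], bulk$truth,
                       gene_ids = rownames(C2))
  fit2 <- nusvr_deconv(bulk2, signature_matrix(C2))
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-10)
  expect_true(all(fit$diagnostics$nu %in% c(0.25, 0.5, 0.75)))
})
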