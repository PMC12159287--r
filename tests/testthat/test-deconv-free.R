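# fixture: bulk with planted pure marker genes, truth P, and noise option
make_marker_bulk <- function(K = 3, M = 90, n = 25, n_markers = 6,
                             noise_sd = 0, seed = 3,
                             p = rep(2, K)) {
  C <- make_separable_C(M = M, K = K, n_markers = n_markers, seed = seed)
  P <- sample_proportions(dirichlet_spec(p, n, seed = seed + 1,
                                         type_names = colnames(C)))
  G <- C %*% P$values
  if (noise_sd > 0) {
    set.seed(seed + 2)
    G <- G * exp(matrix(rnorm(length(G), 0, noise_sd), nrow(G)))
  }
  list(bulk = pseudo_bulk(G, P), C = C,
       markers = rownames(C)[seq_len(K * n_markers)])
}

test_that("mutual-linearity filter keeps marker genes and calibrates the null", {
  fx <- make_marker_bulk(noise_sd = 0.05, seed = 5)
  kept <- collinearity_filter(fx$bulk, top_frac = 0.5, n_perm = 10,
                              seed = 1)
  expect_true(all(fx$markers %in% kept))

  # i.i.d. noise genes survive at about the nominal 5% rate
  set.seed(7)
  noise <- matrix(rexp(1000 * 30), 1000, 30,
                  dimnames = list(sprintf("g%04d", 1:1000), NULL))
  nb <- pseudo_bulk(noise, proportion_matrix(matrix(0.5, 2, 30),
                                             c("a", "b")))
  kept_noise <- collinearity_filter(nb, top_frac = 1, n_perm = 20, seed = 2)
  expect_lt(length(kept_noise) / 1000, 0.12)
  expect_gt(length(kept_noise) / 1000, 0.005)

  # n_perm = 0 keeps exactly top_frac, deterministically
  k1 <- collinearity_filter(fx$bulk, top_frac = 0.2, n_perm = 0)
  k2 <- collinearity_filter(fx$bulk, top_frac = 0.2, n_perm = 0)
  expect_identical(k1, k2)
  expect_length(k1, floor(0.2 * 90))

  two <- pseudo_bulk(noise[, 1:2], proportion_matrix(matrix(0.5, 2, 2),
                                                     c("a", "b")))
  expect_error(collinearity_filter(two), "3 samples")
})

test_that("SVD rank estimation finds the number of types", {
  fx <- make_marker_bulk(K = 3, seed = 9)
  expect_equal(estimate_k(fx$bulk, 0.999), 3)

  rank1 <- pseudo_bulk(outer(seq_len(40), rep(1, 10)) + 0,
                       proportion_matrix(matrix(0.5, 2, 10), c("a", "b")))
  expect_equal(estimate_k(rank1, 0.999), 1)

  expect_lte(estimate_k(fx$bulk, 1), min(dim(fx$bulk$expression)))
  expect_error(estimate_k(fx$bulk, 0), "var_threshold")
})

test_that("simplex corners recover separable noiseless mixtures exactly", {
  fx <- make_marker_bulk(K = 3, n = 25, seed = 13)
  est <- simplex_deconv(fx$bulk, K = 3)
  expect_column_stochastic(est)
  matched <- match_components(est, fx$bulk$truth, method = "simplex")
  expect_lt(max(abs(coef(matched) - fx$bulk$truth$values)), 1e-6)
  # the corners are planted markers
  expect_true(all(attr(est, "corner_genes") %in% fx$markers))
})

test_that("pure samples pin the simplex corners", {
  C <- make_separable_C(M = 60, K = 2, n_markers = 5, seed = 15)
  P <- proportion_matrix(cbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.3, 0.7)),
                         colnames(C))
  bulk <- pseudo_bulk(C %*% P$values, P)
  matched <- match_components(simplex_deconv(bulk, 2), P)
  expect_lt(max(abs(coef(matched) - P$values)), 1e-6)
})

test_that("regularized NMF reduces to plain NMF and never increases the objective", {
  fx <- make_marker_bulk(K = 3, n = 20, noise_sd = 0.1, seed = 17)
  plain <- nmf_marker_deconv(fx$bulk, nmf_config(K = 3, lambda1 = 0,
                                                 lambda2 = 0, n_iter = 120,
                                                 seed = 1))
  again <- nmf_marker_deconv(fx$bulk, nmf_config(K = 3, lambda1 = 0,
                                                 lambda2 = 0, n_iter = 120,
                                                 seed = 1))
  expect_identical(plain$objective, again$objective) # deterministic
  expect_true(all(diff(plain$objective) <=
                    1e-8 * pmax(plain$objective[-length(plain$objective)],
                                1)))

  reg <- nmf_marker_deconv(fx$bulk, nmf_config(
    K = 3, lambda1 = 0.5, lambda2 = 0.05, n_iter = 120, seed = 1,
    marker_candidates = fx$markers))
  expect_true(all(diff(reg$objective) <=
                    1e-8 * pmax(reg$objective[-length(reg$objective)], 1)))
  expect_column_stochastic(reg$proportions)
})

test_that("marker-regularized NMF recovers separable planted mixtures", {
  fx <- make_marker_bulk(K = 3, n = 30, n_markers = 8, seed = 19)
  res <- nmf_marker_deconv(fx$bulk, nmf_config(
    K = 3, lambda1 = 1, lambda2 = 0.1, n_iter = 400, seed = 2,
    marker_candidates = fx$markers))
  matched <- match_components(res$proportions, fx$bulk$truth)
  expect_gt(pearson_r(fx$bulk$truth, matched), 0.99)
})

test_that("component matching recovers permutations and is optimal", {
  P <- sample_proportions(dirichlet_spec(c(2, 1, 1, 0.5), 30, seed = 23))
  # identity
  m0 <- match_components(P, P)
  expect_equal(m0$details$permutation, 1:4)
  expect_equal(sum(m0$diagnostics$match_cor), 4, tolerance = 1e-12)
  # planted permutation
  perm <- c(3, 1, 4, 2)
  Pp <- proportion_matrix(P$values[perm, ], sprintf("component_%d", 1:4))
  m1 <- match_components(Pp, P)
  expect_equal(coef(m1), P$values, ignore_attr = TRUE)
  # optimality: no fixed ordering beats the assignment
  score <- sum(m1$diagnostics$match_cor)
  for (i in 1:5) {
    set.seed(i)
    rnd <- sample(4)
    rnd_score <- sum(vapply(1:4, function(k) {
      stats::cor(Pp$values[rnd[k], ], P$values[k, ])
    }, numeric(1)))
    expect_lte(rnd_score, score + 1e-12)
  }
  bad <- proportion_matrix(matrix(1 / 3, 3, 30))
  expect_error(match_components(bad, P), "mismatch")
})

test_that("reference-free estimates never read the reference copy", {
  fx <- make_marker_bulk(K = 3, n = 20, seed = 27)
  est1 <- simplex_deconv(fx$bulk, 3, seed = 1)
  est2 <- simplex_deconv(fx$bulk, 3, seed = 99)
  expect_identical(est1$values, est2$values) # deterministic, seed-free
  nm1 <- nmf_marker_deconv(fx$bulk, nmf_config(K = 3, n_iter = 50,
                                               seed = 5))
  nm2 <- nmf_marker_deconv(fx$bulk, nmf_config(K = 3, n_iter = 50,
                                               seed = 5))
  expect_identical(nm1$proportions$values, nm2$proportions$values)
})
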