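# Reference-free deconvolution: both C and P of G = C P + e are estimated
# from the bulk matrix alone. Marker genes of a type are (ideally) mutually
# linear -- proportional to that type's fraction across samples -- which
# makes the row-normalized gene vectors live in a (K-1)-simplex whose corners
# are the pure types. Two solvers exploit this geometry: successive-
# projection corner finding, and non-negative matrix factorization
# regularized by marker solvability and a gene-correlation graph.

#' Filter genes by mutual linearity
#'
#' Scores each gene by its maximum Pearson correlation with any other gene
#' across samples; marker genes of the same type are mutually linear and
#' score near 1, while uninformative genes score at noise level. A null
#' distribution is built by `n_perm` independent permutations of each gene's
#' sample order; genes whose score exceeds the null 95th percentile are
#' kept, capped at `top_frac` of genes. With `n_perm = 0` the null is
#' disabled and the top `top_frac` by score is returned deterministically.
#'
#' @param bulk a `pseudo_bulk` with at least 3 samples.
#' @param top_frac maximum fraction of genes retained.
#' @param n_perm number of permutations for the null (0 disables it).
#' @param seed integer seed for the permutations.
#' @return character vector of retained gene ids, ordered by decreasing
#'   score.
#' @export
collinearity_filter <- function(bulk, top_frac = 0.2, n_perm = 20,
                                seed = 1L) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  n <- ncol(bulk$expression)
  if (n < 3) stop("mutual-linearity filtering needs at least 3 samples",
                  call. = FALSE)
  stop_if_not_scalar_number(top_frac, "top_frac", lower = 0, upper = 1,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(n_perm, "n_perm", lower = 0)

  X <- bulk$expression
  ok <- apply(X, 1, stats::sd) > 0
  score <- rep(-Inf, nrow(X))
  if (sum(ok) >= 2) {
    cm <- stats::cor(t(X[ok, , drop = FALSE]))
    diag(cm) <- -Inf
    score[ok] <- apply(cm, 1, max)
  }

  n_cap <- max(1L, floor(top_frac * nrow(X)))
  ord <- order(-score, seq_len(nrow(X)))
  if (n_perm == 0) {
    keep <- ord[seq_len(min(n_cap, sum(is.finite(score))))]
    return(bulk$gene_ids[keep])
  }

  null_scores <- with_seed(child_seed(seed, 4L), {
    Xok <- X[ok, , drop = FALSE]
    unlist(lapply(seq_len(n_perm), function(b) {
      Xp <- t(apply(Xok, 1, sample))
      cm <- stats::cor(t(Xp))
      diag(cm) <- -Inf
      apply(cm, 1, max)
    }))
  })
  thr <- stats::quantile(null_scores, 0.95, names = FALSE)
  keep <- ord[score[ord] > thr]
  keep <- keep[seq_len(min(length(keep), n_cap))]
  bulk$gene_ids[keep]
}

#' Estimate the number of cell types by SVD
#'
#' Returns the smallest K such that the top-K singular values of the
#' column-normalized bulk matrix explain at least `var_threshold` of the
#' total (sum of squared singular values).
#'
#' @param bulk a `pseudo_bulk`.
#' @param var_threshold fraction of variance to explain, in `(0, 1]`.
#' @return an integer K, at most `min(genes, samples)`.
#' @export
estimate_k <- function(bulk, var_threshold = 0.95) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  if (!is.numeric(var_threshold) || length(var_threshold) != 1L ||
      var_threshold <= 0 || var_threshold > 1) {
    stop("`var_threshold` must lie in (0, 1]", call. = FALSE)
  }
  X <- bulk$expression
  tot <- colSums(X)
  if (any(tot <= 0)) stop("degenerate bulk matrix", call. = FALSE)
  Xn <- sweep(X, 2, tot, "/")
  d <- svd(Xn, nu = 0, nv = 0)$d
  frac <- cumsum(d^2) / sum(d^2)
  as.integer(which(frac >= var_threshold - 1e-12)[1])
}

# successive projection: greedily pick the row of Y with maximal residual
# norm, deflate all rows by its direction, repeat K times; exact on
# separable (pure-marker) data
successive_projection <- function(Y, K) {
  R <- Y
  picked <- integer(K)
  for (k in seq_len(K)) {
    norms <- rowSums(R^2)
    norms[picked[seq_len(k - 1)]] <- -Inf
    picked[k] <- which.max(norms)
    u <- R[picked[k], ]
    nu2 <- sum(u^2)
    if (nu2 <= 0) stop("degenerate geometry: zero residual before K corners",
                       call. = FALSE)
    R <- R - (R %*% u) %*% t(u) / nu2
  }
  picked
}

#' Simplex-corner deconvolution
#'
#' Each gene's expression is normalized across samples to sum 1; the
#' normalized rows are convex combinations of the K pure-type rows, so they
#' lie in a (K-1)-simplex whose corners are marker genes. The rows are
#' denoised by projection onto the top-K singular subspace, the corners are
#' located by the successive-projection (maximum residual norm) rule, and
#' per-type scales are recovered by non-negative regression of the
#' all-ones vector on the corner rows (enforcing that compositions sum to 1
#' in every sample); the rescaled corner rows, column-normalized, are the
#' estimated proportions.
#'
#' @param bulk a `pseudo_bulk` with at least K samples.
#' @param K number of cell types (>= 2).
#' @param seed accepted for interface uniformity; the solver is
#'   deterministic.
#' @return a [proportion_matrix()] with anonymous component labels
#'   (`component_1`, ...); the corner gene ids are attached as attribute
#'   `corner_genes`.
#' @export
simplex_deconv <- function(bulk, K, seed = 1L) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  stop_if_not_scalar_number(K, "K", lower = 2)
  n <- ncol(bulk$expression)
  if (n < K) stop("need at least K samples", call. = FALSE)
  X <- bulk$expression
  rs <- rowSums(X)
  use <- rs > 0 & apply(X, 1, stats::sd) > 0
  if (sum(use) < K) stop("degenerate geometry: too few informative genes",
                         call. = FALSE)
  Y <- sweep(X[use, , drop = FALSE], 1, rowSums(X[use, , drop = FALSE]), "/")

  # rank-K denoising before corner search
  sv <- svd(Y, nu = K, nv = K)
  Yk <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v))

  corners <- successive_projection(Yk, K)
  corner_rows <- X[use, , drop = FALSE][corners, , drop = FALSE]
  if (qr(corner_rows)$rank < K) {
    stop("degenerate geometry: corner rows are rank-deficient",
         call. = FALSE)
  }

  # marker row k is proportional to c_k * p_k.; find u >= 0 with
  # sum_k u_k * row_k = 1 for all samples, i.e. recover per-type scales
  sol <- pracma::lsqnonneg(t(corner_rows) / mean(corner_rows), rep(1, n))
  u <- sol$x / mean(corner_rows)
  if (any(u <= 0)) {
    # fall back to row-sum scaling when the scale regression degenerates
    u <- 1 / rowSums(corner_rows)
  }
  P <- u * corner_rows
  P <- sweep(pmax(P, 0), 2, colSums(P), "/")
  rownames(P) <- sprintf("component_%d", seq_len(K))
  colnames(P) <- bulk$sample_ids
  out <- proportion_matrix(P)
  attr(out, "corner_genes") <- bulk$gene_ids[use][corners]
  out
}

#' Configuration for regularized NMF deconvolution
#'
#' @param K number of components.
#' @param lambda1 weight of the marker-solvability penalty: for each
#'   candidate marker gene, the squared off-dominant loadings of its
#'   signature row are penalized.
#' @param lambda2 weight of the graph penalty `trace(C' L C)`, where L is
#'   the Laplacian of the gene-gene correlation graph (edges between
#'   filtered genes with correlation above `cor_threshold`).
#' @param n_iter maximum multiplicative updates.
#' @param tol relative objective-change stopping tolerance.
#' @param seed integer seed (controls the fallback random initialization).
#' @param marker_candidates optional character vector of candidate marker
#'   gene ids used by both penalties; when `NULL`, the mutual-linearity
#'   filter selects them.
#' @param cor_threshold correlation threshold for graph edges.
#' @return an object of class `nmf_config`.
#' @export
nmf_config <- function(K, lambda1 = 0, lambda2 = 0, n_iter = 500,
                       tol = 1e-8, seed = 1L, marker_candidates = NULL,
                       cor_threshold = 0.9) {
  stop_if_not_scalar_number(K, "K", lower = 2)
  stop_if_not_scalar_number(lambda1, "lambda1", lower = 0)
  stop_if_not_scalar_number(lambda2, "lambda2", lower = 0)
  stop_if_not_scalar_number(n_iter, "n_iter", lower = 1)
  stop_if_not_scalar_number(tol, "tol", lower = 0)
  structure(list(K = as.integer(K), lambda1 = lambda1, lambda2 = lambda2,
                 n_iter = as.integer(n_iter), tol = tol,
                 seed = as.integer(seed),
                 marker_candidates = marker_candidates,
                 cor_threshold = cor_threshold),
            class = "nmf_config")
}

# non-negative double SVD initialization (deterministic); zeros are replaced
# by a small positive value so multiplicative updates can move them
nndsvd_init <- function(G, K, seed) {
  sv <- tryCatch(svd(G, nu = K, nv = K), error = function(e) NULL)
  M <- nrow(G)
  n <- ncol(G)
  if (is.null(sv) || length(sv$d) < K) {
    return(with_seed(child_seed(seed, 5L), {
      s <- sqrt(mean(G) / K)
      list(C = matrix(stats::runif(M * K, 0, s), M, K),
           P = matrix(stats::runif(K * n, 0, s), K, n))
    }))
  }
  C <- matrix(0, M, K)
  P <- matrix(0, K, n)
  C[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  P[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (k in seq_len(K)[-1]) {
    u <- sv$u[, k]
    v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (n_p >= n_n && n_p > 0) {
      C[, k] <- sqrt(sv$d[k] * n_p) * up / sqrt(sum(up^2))
      P[k, ] <- sqrt(sv$d[k] * n_p) * vp / sqrt(sum(vp^2))
    } else if (n_n > 0) {
      C[, k] <- sqrt(sv$d[k] * n_n) * un / sqrt(sum(un^2))
      P[k, ] <- sqrt(sv$d[k] * n_n) * vn / sqrt(sum(vn^2))
    }
  }
  floor_val <- mean(G) * 1e-4 + 1e-12
  C[C < floor_val] <- floor_val
  P[P < floor_val] <- floor_val
  list(C = C, P = P)
}

#' Marker- and graph-regularized NMF deconvolution
#'
#' Minimizes `||G - C P||_F^2 + lambda1 F1(C) + lambda2 trace(C' L C)` over
#' `C, P >= 0` by multiplicative updates. `F1` is a marker-solvability
#' penalty: for every candidate marker gene, the squared entries of its row
#' of C outside the dominant component (fixed at initialization) are
#' penalized, pushing markers toward single-type loading. `L = D - W` is the
#' unnormalized Laplacian of the gene-gene correlation graph, with edges
#' between candidate genes whose expression correlation exceeds
#' `cor_threshold`; the trace term smooths the signature over that graph.
#' These penalty forms are this package's instantiation of marker
#' solvability and manifold regularization. Initialization is deterministic
#' non-negative double SVD with a seed-controlled uniform fallback.
#'
#' @param bulk a `pseudo_bulk` (non-negative expression).
#' @param cfg an [nmf_config()].
#' @return a list with `signature` (estimated genes x K matrix),
#'   `proportions` (a [proportion_matrix()] with anonymous components),
#'   `objective` (per-iteration trace) and `converged`.
#' @export
nmf_marker_deconv <- function(bulk, cfg) {
  stopifnot(inherits(bulk, "pseudo_bulk"), inherits(cfg, "nmf_config"))
  G <- bulk$expression
  if (any(G < 0)) stop("NMF requires a non-negative matrix", call. = FALSE)
  # work on a common scale so penalty weights are comparable across inputs
  gscale <- mean(G)
  if (gscale <= 0) stop("empty bulk matrix", call. = FALSE)
  G <- G / gscale
  M <- nrow(G)
  n <- ncol(G)
  K <- cfg$K
  eps <- 1e-12

  candidates <- cfg$marker_candidates
  if (is.null(candidates) && (cfg$lambda1 > 0 || cfg$lambda2 > 0)) {
    candidates <- collinearity_filter(bulk, top_frac = 0.2, n_perm = 0)
  }
  cand_idx <- match(intersect(candidates, bulk$gene_ids), bulk$gene_ids)

  # graph Laplacian on candidate genes
  W <- NULL
  dW <- NULL
  if (cfg$lambda2 > 0 && length(cand_idx) >= 2) {
    cm <- stats::cor(t(bulk$expression[cand_idx, , drop = FALSE]))
    cm[is.na(cm)] <- 0
    A <- (cm > cfg$cor_threshold) * 1
    diag(A) <- 0
    W <- Matrix::sparseMatrix(
      i = rep(cand_idx, times = ncol(A)),
      j = rep(cand_idx, each = nrow(A)),
      x = as.vector(A), dims = c(M, M))
    dW <- Matrix::rowSums(W)
  }

  init <- nndsvd_init(G, K, cfg$seed)
  C <- init$C
  P <- init$P

  # solvability mask: candidate markers of one cell type are mutually linear
  # across samples, so cluster the candidates into K correlation groups and
  # dedicate one component to each group; off-group loadings of a candidate
  # row are penalized, and the initialization is seeded to the same layout
  mask <- NULL
  if (cfg$lambda1 > 0 && length(cand_idx) >= K) {
    cc <- stats::cor(t(bulk$expression[cand_idx, , drop = FALSE]))
    cc[is.na(cc)] <- 0
    grp <- stats::cutree(stats::hclust(stats::as.dist(1 - cc),
                                       method = "average"), k = K)
    mask <- matrix(0, M, K)
    mask[cand_idx, ] <- 1
    mask[cbind(cand_idx, grp)] <- 0
    floor_val <- max(mean(G) * 1e-4, 1e-12)
    rs <- rowSums(C[cand_idx, , drop = FALSE])
    C[cand_idx, ] <- floor_val
    C[cbind(cand_idx, grp)] <- pmax(rs, floor_val)
  }

  objective <- function(C, P) {
    obj <- sum((G - C %*% P)^2)
    if (!is.null(mask)) obj <- obj + cfg$lambda1 * sum((mask * C)^2)
    if (!is.null(W)) {
      obj <- obj + cfg$lambda2 * (sum(dW * Matrix::rowSums(C * C)) -
                                    sum(C * as.matrix(W %*% C)))
    }
    obj
  }

  obj_trace <- numeric(cfg$n_iter)
  prev <- objective(C, P)
  converged <- FALSE
  for (it in seq_len(cfg$n_iter)) {
    # update C
    num <- G %*% t(P)
    den <- C %*% (P %*% t(P))
    if (!is.null(mask)) den <- den + cfg$lambda1 * (mask * C)
    if (!is.null(W)) {
      num <- num + cfg$lambda2 * as.matrix(W %*% C)
      den <- den + cfg$lambda2 * (dW * C)
    }
    C <- C * num / (den + eps)
    # update P
    P <- P * (t(C) %*% G) / (t(C) %*% C %*% P + eps)

    obj <- objective(C, P)
    obj_trace[it] <- obj
    if (obj > prev * (1 + 1e-6) + 1e-10) {
      stop(sprintf("objective increased at iteration %d (%.6g -> %.6g)",
                   it, prev, obj), call. = FALSE)
    }
    if (abs(prev - obj) < cfg$tol * max(prev, eps)) {
      converged <- TRUE
      obj_trace <- obj_trace[seq_len(it)]
      break
    }
    prev <- obj
  }

  cs <- colSums(P)
  cs[cs == 0] <- 1
  Pn <- sweep(P, 2, cs, "/")
  rownames(Pn) <- sprintf("component_%d", seq_len(K))
  colnames(Pn) <- bulk$sample_ids
  sig <- C * gscale
  dimnames(sig) <- list(bulk$gene_ids, rownames(Pn))
  list(signature = sig,
       proportions = proportion_matrix(Pn),
       objective = obj_trace,
       converged = converged)
}

#' Match anonymous components to true cell types
#'
#' Reference-free estimates carry arbitrary component labels. This finds the
#' one-to-one assignment of components to truth rows maximizing the sum of
#' per-component Pearson correlations (exact enumeration for K <= 8, greedy
#' above) and returns the estimate with rows permuted into the truth's
#' order.
#'
#' @param est a [proportion_matrix()] with anonymous components.
#' @param truth the ground-truth [proportion_matrix()] (same K and number of
#'   samples).
#' @param method label recorded on the returned fit.
#' @return a `deconv_fit` whose `proportions` rows are aligned with
#'   `truth$type_names`; `details$permutation` maps truth row k to the
#'   matched component index.
#' @export
match_components <- function(est, truth, method = "reference_free") {
  stopifnot(inherits(est, "proportion_matrix"),
            inherits(truth, "proportion_matrix"))
  K <- nrow(est$values)
  if (K != nrow(truth$values)) stop("component count mismatch",
                                    call. = FALSE)
  if (ncol(est$values) != ncol(truth$values)) {
    stop("sample count mismatch", call. = FALSE)
  }
  # correlation of every (component, truth row) pair; constant rows get 0
  cmat <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (k in seq_len(K)) {
      e <- est$values[i, ]
      t_ <- truth$values[k, ]
      if (stats::sd(e) > 0 && stats::sd(t_) > 0) {
        cmat[i, k] <- stats::cor(e, t_)
      }
    }
  }
  perm <- best_assignment(cmat)
  P <- est$values[perm, , drop = FALSE]
  rownames(P) <- truth$type_names
  new_deconv_fit(proportion_matrix(P, truth$type_names), method,
                 data.frame(type = truth$type_names, component = perm,
                            match_cor = cmat[cbind(perm, seq_len(K))]),
                 details = list(permutation = perm, cor_matrix = cmat))
}

# exact assignment for small K (enumeration), greedy otherwise;
# cmat[i, k] = score of assigning component i to truth row k, perm[k] = i
best_assignment <- function(cmat) {
  K <- nrow(cmat)
  if (K <= 8) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p) sum(cmat[cbind(p, seq_len(K))]),
                     numeric(1))
    perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    avail <- rep(TRUE, K)
    for (k in order(-apply(cmat, 2, max))) {
      i <- which.max(ifelse(avail, cmat[, k], -Inf))
      perm[k] <- i
      avail[i] <- FALSE
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- vector("list", K * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(K)) {
      out[[idx]] <- append(p, K, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
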