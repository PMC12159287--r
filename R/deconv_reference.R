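# Reference-based deconvolution of the mixing model G = C P + e: a signature
# matrix C is estimated from a labelled cell-level reference and each bulk
# sample's composition is recovered by constrained regression. Three solver
# families are provided: plain non-negative least squares, variance-weighted
# NNLS (genes with low within-type and high between-type variance dominate),
# and linear nu-support-vector regression on the standardized signature.

#' Construct a signature matrix
#'
#' @param values genes x K non-negative matrix of expected per-type
#'   expression.
#' @param gene_ids signature gene identifiers (rows).
#' @param type_names cell-type labels (columns), K >= 2.
#' @param within_var optional genes x K matrix of within-type variances
#'   (used by the weighted solver).
#' @return an object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, gene_ids = rownames(values),
                             type_names = colnames(values),
                             within_var = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(type_names)) {
    stop("signature needs gene and type identifiers", call. = FALSE)
  }
  if (ncol(values) < 2) stop("a signature needs at least 2 types",
                             call. = FALSE)
  if (any(values < 0) || any(!is.finite(values))) {
    stop("signature values must be non-negative and finite", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, type_names)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 type_names = as.character(type_names),
                 within_var = within_var),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes x %d types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a signature matrix from a labelled reference
#'
#' Cells are first normalized to equal totals (the mean library size), then
#' each type's column is the mean profile over its cells. Marker genes are
#' selected per type by the Welch two-sample t statistic of the type against
#' all other cells; the `n_markers_per_type` genes with the largest statistic
#' per type are kept (ties broken by gene order) and the union of the
#' selections forms the signature rows.
#'
#' @param reference a `single_cell_dataset` with K >= 2 types, each with at
#'   least 2 cells.
#' @param n_markers_per_type number of marker genes selected per type.
#' @return a [signature_matrix()] carrying within-type variances of the
#'   normalized reference for downstream weighting.
#' @export
build_signature <- function(reference, n_markers_per_type = 50) {
  stopifnot(inherits(reference, "single_cell_dataset"))
  K <- length(reference$type_names)
  if (K < 2) stop("reference must contain at least 2 types", call. = FALSE)
  tab <- table(factor(reference$cell_types, levels = reference$type_names))
  if (any(tab < 2)) stop("every type needs at least 2 cells", call. = FALSE)
  M <- nrow(reference$counts)
  stop_if_not_scalar_number(n_markers_per_type, "n_markers_per_type",
                            lower = 1, upper = M)

  totals <- colSums(reference$counts)
  if (any(totals <= 0)) stop("reference contains empty cells", call. = FALSE)
  norm <- sweep(reference$counts, 2, totals / mean(totals), "/")

  means <- matrix(0, M, K)
  vars <- matrix(0, M, K)
  ns <- integer(K)
  for (k in seq_len(K)) {
    cols <- reference$cell_types == reference$type_names[k]
    ns[k] <- sum(cols)
    x <- norm[, cols, drop = FALSE]
    means[, k] <- rowMeans(x)
    vars[, k] <- apply(x, 1, stats::var)
  }

  eps <- 1e-8
  selected <- integer(0)
  for (k in seq_len(K)) {
    rest <- setdiff(seq_len(K), k)
    n_rest <- sum(ns[rest])
    m_rest <- means[, rest, drop = FALSE] %*% (ns[rest] / n_rest)
    # pooled 'rest' variance via the law of total variance over types
    ev <- vars[, rest, drop = FALSE] %*% (ns[rest] / n_rest)
    vm <- (means[, rest, drop = FALSE] - as.vector(m_rest))^2 %*%
      (ns[rest] / n_rest)
    v_rest <- as.vector(ev + vm)
    tstat <- (means[, k] - as.vector(m_rest)) /
      sqrt(vars[, k] / ns[k] + v_rest / n_rest + eps)
    ord <- order(-tstat, seq_len(M)) # ties broken by gene order
    selected <- union(selected, ord[seq_len(n_markers_per_type)])
  }
  selected <- sort(selected) # keep gene order in the signature

  signature_matrix(means[selected, , drop = FALSE],
                   gene_ids = reference$gene_ids[selected],
                   type_names = reference$type_names,
                   within_var = {
                     wv <- vars[selected, , drop = FALSE]
                     dimnames(wv) <- list(reference$gene_ids[selected],
                                          reference$type_names)
                     wv
                   })
}

# align a pseudo_bulk and a signature on their shared genes
shared_genes <- function(bulk, sig) {
  common <- intersect(bulk$gene_ids, sig$gene_ids)
  if (length(common) == 0) stop("no shared genes between bulk and signature",
                                call. = FALSE)
  if (length(common) < length(sig$type_names)) {
    stop("fewer shared genes than cell types", call. = FALSE)
  }
  list(G = bulk$expression[match(common, bulk$gene_ids), , drop = FALSE],
       C = sig$values[match(common, sig$gene_ids), , drop = FALSE],
       genes = common)
}

new_deconv_fit <- function(proportions, method, diagnostics, fitted = NULL,
                           observed = NULL, details = list()) {
  structure(list(proportions = proportions, method = method,
                 diagnostics = diagnostics, fitted = fitted,
                 observed = observed, details = details),
            class = "deconv_fit")
}

#' Non-negative least squares deconvolution
#'
#' Solves, per sample, `min || C p - g ||_2` subject to `p >= 0`
#' (Lawson-Hanson NNLS) on the genes shared between the bulk and the
#' signature, then rescales the solution to the simplex.
#'
#' @param bulk a `pseudo_bulk`.
#' @param sig a [signature_matrix()].
#' @return a `deconv_fit` whose `proportions` are a [proportion_matrix()];
#'   `diagnostics` holds the per-sample residual norm.
#' @export
nnls_deconv <- function(bulk, sig) {
  stopifnot(inherits(bulk, "pseudo_bulk"), inherits(sig, "signature_matrix"))
  al <- shared_genes(bulk, sig)
  K <- ncol(al$C)
  if (qr(al$C)$rank < K) {
    warning("signature is rank-deficient on shared genes; ",
            "estimates may be unstable")
  }
  n <- ncol(al$G)
  P <- matrix(0, K, n)
  resid <- numeric(n)
  for (j in seq_len(n)) {
    g <- al$G[, j]
    if (all(g == 0)) stop(sprintf("degenerate sample %d: all-zero profile",
                                  j), call. = FALSE)
    sol <- pracma::lsqnonneg(al$C, g)
    if (sum(sol$x) <= 0) {
      stop(sprintf("degenerate sample %d: all-zero NNLS solution", j),
           call. = FALSE)
    }
    P[, j] <- sol$x / sum(sol$x)
    resid[j] <- sqrt(sum((al$C %*% sol$x - g)^2))
  }
  colnames(P) <- bulk$sample_ids
  new_deconv_fit(proportion_matrix(P, sig$type_names), "nnls",
                 data.frame(sample_id = bulk$sample_ids, resid_norm = resid),
                 fitted = al$C %*% P, observed = al$G,
                 details = list(genes = al$genes))
}

#' Variance-weighted non-negative least squares deconvolution
#'
#' Iterative weighted NNLS in the spirit of cross-subject single-cell
#' weighting schemes: the weight of gene g is
#' `between-type variance / (pooled within-type variance + residual variance
#' + eps)`, so genes that are stable within a type but discriminative across
#' types dominate the fit. Starting from equal residual variances, each pass
#' solves weighted NNLS per sample and re-estimates the per-gene residual
#' variance from the current fit.
#'
#' @param bulk a `pseudo_bulk`.
#' @param reference a `single_cell_dataset` supplying both the signature and
#'   the within-type variances.
#' @param n_iter maximum number of reweighting passes.
#' @param n_markers_per_type passed to [build_signature()].
#' @param tol convergence tolerance on the proportion update.
#' @param eps_reg regularizer preventing division by zero in the weights.
#' @return a `deconv_fit`; `details$converged` flags samples that did not
#'   converge within `n_iter` (their last iterate is returned).
#' @export
wnnls_deconv <- function(bulk, reference, n_iter = 100,
                         n_markers_per_type = 50, tol = 1e-6,
                         eps_reg = 1e-8) {
  stopifnot(inherits(bulk, "pseudo_bulk"),
            inherits(reference, "single_cell_dataset"))
  sig <- build_signature(reference, n_markers_per_type)
  al <- shared_genes(bulk, sig)
  wv <- sig$within_var[match(al$genes, sig$gene_ids), , drop = FALSE]
  K <- ncol(al$C)
  n <- ncol(al$G)

  between <- apply(al$C, 1, stats::var)
  within <- rowMeans(wv)

  P <- matrix(0, K, n)
  resid <- numeric(n)
  converged <- logical(n)
  for (j in seq_len(n)) {
    g <- al$G[, j]
    if (all(g == 0)) stop(sprintf("degenerate sample %d: all-zero profile",
                                  j), call. = FALSE)
    sigma2 <- rep(0, length(g)) # residual variance, re-estimated each pass
    p_prev <- rep(Inf, K)
    x <- rep(0, K)
    for (it in seq_len(n_iter)) {
      w <- between / (within + sigma2 + eps_reg)
      sw <- sqrt(w)
      sol <- pracma::lsqnonneg(al$C * sw, g * sw)
      x <- sol$x
      r <- g - as.vector(al$C %*% x)
      sigma2 <- r^2
      p_now <- if (sum(x) > 0) x / sum(x) else x
      if (max(abs(p_now - p_prev)) < tol) {
        converged[j] <- TRUE
        break
      }
      p_prev <- p_now
    }
    if (sum(x) <= 0) {
      stop(sprintf("degenerate sample %d: all-zero w-NNLS solution", j),
           call. = FALSE)
    }
    P[, j] <- x / sum(x)
    resid[j] <- sqrt(sum((g - as.vector(al$C %*% x))^2))
  }
  if (!all(converged)) {
    warning(sprintf("w-NNLS did not converge for %d/%d samples within %d passes",
                    sum(!converged), n, n_iter))
  }
  colnames(P) <- bulk$sample_ids
  new_deconv_fit(proportion_matrix(P, sig$type_names), "wnnls",
                 data.frame(sample_id = bulk$sample_ids, resid_norm = resid,
                            converged = converged),
                 fitted = al$C %*% P, observed = al$G,
                 details = list(genes = al$genes, signature = sig))
}

#' nu-support-vector regression deconvolution
#'
#' Per sample: duplicated signature/observation rows are collapsed, the
#' sample and the signature are standardized (the sample across genes; the
#' signature by its global mean and SD, preserving the relative geometry of
#' its columns), and a linear nu-SVR of the sample on the signature columns
#' is fitted for every nu in `nu_grid`. The nu minimizing the root-mean-
#' square fit error is kept; negative coefficients are clipped to zero and
#' the rest renormalized to the simplex.
#'
#' @param bulk a `pseudo_bulk`.
#' @param sig a [signature_matrix()].
#' @param nu_grid candidate nu values (default the published CIBERSORT grid
#'   0.25/0.5/0.75).
#' @return a `deconv_fit`; samples whose coefficients all clip to zero are
#'   flagged `failed` in `diagnostics` and returned as uniform proportions.
#' @export
nusvr_deconv <- function(bulk, sig, nu_grid = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(bulk, "pseudo_bulk"), inherits(sig, "signature_matrix"))
  al <- shared_genes(bulk, sig)
  K <- ncol(al$C)
  n <- ncol(al$G)
  P <- matrix(0, K, n)
  resid <- numeric(n)
  failed <- logical(n)
  best_nu <- numeric(n)
  for (j in seq_len(n)) {
    g <- al$G[, j]
    key <- paste(apply(al$C, 1, paste, collapse = "\r"), g, sep = "\r")
    keep <- !duplicated(key)
    X <- al$C[keep, , drop = FALSE]
    y <- g[keep]
    if (stats::sd(y) == 0) {
      stop(sprintf("degenerate sample %d: constant profile", j),
           call. = FALSE)
    }
    ys <- (y - mean(y)) / stats::sd(y)
    Xs <- (X - mean(X)) / stats::sd(as.vector(X))
    best <- NULL
    best_rmse <- Inf
    for (nu in nu_grid) {
      fit <- e1071::svm(x = Xs, y = ys, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      w <- as.vector(t(fit$coefs) %*% fit$SV)
      pred <- as.vector(Xs %*% w) - fit$rho
      rmse <- sqrt(mean((ys - pred)^2))
      if (rmse < best_rmse) {
        best_rmse <- rmse
        best <- list(w = w, nu = nu)
      }
    }
    w <- pmax(best$w, 0)
    if (sum(w) == 0) {
      failed[j] <- TRUE
      P[, j] <- rep(1 / K, K)
    } else {
      P[, j] <- w / sum(w)
    }
    best_nu[j] <- best$nu
    resid[j] <- best_rmse
  }
  if (any(failed)) {
    warning(sprintf("nu-SVR clipped all coefficients for %d samples; %s",
                    sum(failed), "uniform proportions substituted"))
  }
  colnames(P) <- bulk$sample_ids
  new_deconv_fit(proportion_matrix(P, sig$type_names), "nusvr",
                 data.frame(sample_id = bulk$sample_ids, resid_norm = resid,
                            nu = best_nu, failed = failed),
                 fitted = al$C %*% P, observed = al$G,
                 details = list(genes = al$genes))
}
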