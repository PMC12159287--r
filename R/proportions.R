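# Dirichlet model for ground-truth cell-type compositions. The concentration
# vector p determines both the expected composition gamma_k = p_k / p0 and,
# through its sum p0, the compositional variance: dividing p by a constant
# keeps gamma fixed and inflates the variance.

#' Construct a proportion matrix
#'
#' A K x n column-stochastic matrix of cell-type proportions; columns are
#' samples, rows are cell types.
#'
#' @param values K x n numeric matrix; every column must sum to 1 within
#'   1e-12 and entries must lie in `[0, 1]`.
#' @param type_names ordered labels for the K rows.
#' @return an object of class `proportion_matrix`.
#' @export
proportion_matrix <- function(values, type_names = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(type_names)) {
    type_names <- sprintf("type_%d", seq_len(nrow(values)))
  }
  stopifnot(length(type_names) == nrow(values))
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  cs <- colSums(values)
  if (any(abs(cs - 1) > 1e-8)) {
    stop("every column of a proportion matrix must sum to 1", call. = FALSE)
  }
  values <- sweep(values, 2, cs, "/") # remove residual rounding
  rownames(values) <- type_names
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  }
  structure(list(values = values, type_names = as.character(type_names)),
            class = "proportion_matrix")
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("proportion_matrix: %d types x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  row means:",
      paste(sprintf("%s=%.3f", x$type_names, rowMeans(x$values)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Dirichlet sampling specification
#'
#' @param p length-K vector of positive concentration parameters.
#' @param n_samples number of composition draws.
#' @param seed integer seed.
#' @param type_names optional labels for the K types.
#' @return an object of class `dirichlet_spec`.
#' @export
dirichlet_spec <- function(p, n_samples, seed = 1L, type_names = names(p)) {
  if (!is.numeric(p) || length(p) < 1 || any(!is.finite(p)) || any(p <= 0)) {
    stop("all concentration parameters must be positive and finite",
         call. = FALSE)
  }
  stop_if_not_scalar_number(n_samples, "n_samples", lower = 1)
  if (is.null(type_names)) type_names <- sprintf("type_%d", seq_along(p))
  structure(list(p = as.numeric(p), n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 type_names = as.character(type_names)),
            class = "dirichlet_spec")
}

#' Expected composition of a Dirichlet model
#'
#' Returns `gamma_k = p_k / sum(p)`, the expected proportion of each cell
#' type. Invariant under rescaling of `p`.
#'
#' @param p positive concentration vector.
#' @return a simplex vector of the same length as `p`.
#' @examples
#' expected_proportions(c(5.4, 3.5, 1.1, 0.5)) # pancreatic islet preset
#' @export
expected_proportions <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0)) {
    stop("all concentration parameters must be positive", call. = FALSE)
  }
  p / sum(p)
}

#' Marginal variance of Dirichlet proportions
#'
#' The marginal of component k is Beta(p_k, p0 - p_k), so its variance is
#' `gamma_k (1 - gamma_k) / (p0 + 1)` with `p0 = sum(p)`. For fixed expected
#' composition the variance is strictly decreasing in `p0`, which is how the
#' small/medium/large variation tiers (p, p/10, p/100) are constructed.
#'
#' @param p positive concentration vector.
#' @return per-type marginal variances.
#' @export
proportion_variance <- function(p) {
  g <- expected_proportions(p)
  g * (1 - g) / (sum(p) + 1)
}

#' Sample compositions from a Dirichlet model
#'
#' Draws are generated as normalized independent Gamma(p_k, 1) variates,
#' the standard construction of the Dirichlet distribution.
#'
#' @param spec a [dirichlet_spec()].
#' @return a [proportion_matrix()] with `n_samples` columns; deterministic
#'   for a fixed seed.
#' @export
sample_proportions <- function(spec) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  K <- length(spec$p)
  vals <- with_seed(child_seed(spec$seed, 2L), {
    g <- matrix(stats::rgamma(K * spec$n_samples, shape = spec$p, rate = 1),
                K, spec$n_samples)
    sweep(g, 2, colSums(g), "/")
  })
  proportion_matrix(vals, spec$type_names)
}

# Concentration vectors used in the benchmark, one per tissue design, with
# the three variation tiers obtained by dividing by 1, 10 and 100.
.dirichlet_presets <- list(
  mixture = list( # rat liver / brain / lung pure-cell mixture design
    p = c(3.3, 3.4, 3.3),
    types = c("liver", "brain", "lung")
  ),
  blood = list( # six grouped leukocyte types of the LM22-style design
    p = c(1, 2.5, 0.5, 0.8, 0.5, 0.5),
    types = c("B", "T", "NK", "macrophage", "dendritic", "mast")
  ),
  pancreas = list( # pancreatic islet design (alpha, beta, gamma, delta)
    p = c(5.4, 3.5, 1.1, 0.5),
    types = c("alpha", "beta", "gamma", "delta")
  ),
  brain = list( # human brain design
    p = c(6.2, 2, 1.6, 13.1, 3.8),
    types = c("astrocyte", "endothelial", "microglia", "neuron",
              "oligodendrocyte")
  )
)

#' Benchmark concentration presets
#'
#' Ships the concentration vectors of the four tissue designs used in the
#' benchmark together with the three composition-variance tiers: the `small`
#' tier uses the vector as printed, `medium` divides it by 10 and `large` by
#' 100 (same expected composition, increasing variance).
#'
#' @param tissue one of `"mixture"` (liver/brain/lung), `"blood"`,
#'   `"pancreas"`, `"brain"`.
#' @param tier one of `"small"`, `"medium"`, `"large"`.
#' @return a list with elements `p` (concentration vector, named by cell
#'   type), `gamma` (expected composition) and `tier`.
#' @examples
#' dirichlet_preset("pancreas", "medium")$p
#' @export
dirichlet_preset <- function(tissue = c("mixture", "blood", "pancreas",
                                        "brain"),
                             tier = c("small", "medium", "large")) {
  tissue <- match.arg(tissue)
  tier <- match.arg(tier)
  div <- c(small = 1, medium = 10, large = 100)[[tier]]
  base <- .dirichlet_presets[[tissue]]
  p <- base$p / div
  names(p) <- base$types
  list(p = p, gamma = expected_proportions(p), tier = tier, tissue = tissue)
}
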