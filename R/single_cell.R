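# Synthetic cell-level expression data with planted marker structure, plus the
# controlled discrepancy operators applied between the bulk-generating and
# reference copies of the data.

#' Specification for a synthetic cell-level dataset
#'
#' Describes a genes x cells count dataset with `n_types` cell types. Each
#' type owns a disjoint block of marker genes whose expected expression is
#' elevated `marker_fold`-fold in that type. Counts are negative-binomial
#' around a per-gene baseline, scaled by a per-cell log-normal library-size
#' factor, which mimics the overdispersion and depth variation of real
#' scRNA-seq count data.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_type cells per type; a scalar or a length-`n_types`
#'   vector.
#' @param n_types number of cell types K.
#' @param marker_frac fraction of genes designated markers of each type;
#'   marker sets are disjoint, so `marker_frac * n_types` must be <= 1.
#' @param marker_fold multiplicative elevation (> 1) of a marker gene in its
#'   own type.
#' @param base_mean baseline expected count per gene per cell.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson counts.
#' @param libsize_sigma standard deviation, on the log scale, of the per-cell
#'   library-size factor (mean 1); 0 disables library-size variation.
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#'
#' @return an object of class `single_cell_spec`.
#' @seealso [generate_single_cell_dataset()]
#' @export
single_cell_spec <- function(n_genes = 2000, n_cells_per_type = 100,
                             n_types = 4, marker_frac = 0.05,
                             marker_fold = 8, base_mean = 3,
                             dispersion = 0.3, libsize_sigma = 0.3,
                             seed = 1L) {
  stop_if_not_scalar_number(n_genes, "n_genes", lower = 1)
  stop_if_not_scalar_number(n_types, "n_types", lower = 1)
  if (!is.numeric(n_cells_per_type) ||
      !length(n_cells_per_type) %in% c(1L, n_types) ||
      any(n_cells_per_type < 1)) {
    stop("`n_cells_per_type` must be positive, length 1 or n_types",
         call. = FALSE)
  }
  stop_if_not_scalar_number(marker_frac, "marker_frac", lower = 0, upper = 1)
  if (marker_frac * n_types > 1) {
    stop("marker_frac * n_types > 1: disjoint marker sets are impossible",
         call. = FALSE)
  }
  stop_if_not_scalar_number(marker_fold, "marker_fold", lower = 1,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(base_mean, "base_mean", lower = 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(dispersion, "dispersion", lower = 0)
  stop_if_not_scalar_number(libsize_sigma, "libsize_sigma", lower = 0)
  stop_if_not_scalar_number(seed, "seed")
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_cells_per_type = as.integer(rep_len(n_cells_per_type, n_types)),
      n_types = as.integer(n_types),
      marker_frac = marker_frac,
      marker_fold = marker_fold,
      base_mean = base_mean,
      dispersion = dispersion,
      libsize_sigma = libsize_sigma,
      seed = as.integer(seed)
    ),
    class = "single_cell_spec"
  )
}

#' Construct a cell-level dataset from components
#'
#' Assembles a genes x cells count matrix with per-cell type labels into the
#' container used throughout the package, validating its invariants
#' (non-negative finite counts, unique gene ids, every cell labelled, every
#' type populated). Use this to wrap your own cell-level data;
#' [generate_single_cell_dataset()] is the synthetic route.
#'
#' @param counts genes x cells non-negative matrix.
#' @param gene_ids unique gene identifiers (defaults to rownames).
#' @param cell_types per-cell type label.
#' @param type_names ordered type labels (defaults to the order of first
#'   appearance in `cell_types`).
#' @return an object of class `single_cell_dataset`.
#' @export
single_cell_dataset <- function(counts, gene_ids = rownames(counts),
                                cell_types,
                                type_names = unique(cell_types)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  new_single_cell_dataset(counts, gene_ids, cell_types, type_names)
}

new_single_cell_dataset <- function(counts, gene_ids, cell_types, type_names,
                                    marker_sets = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == length(gene_ids),
            ncol(counts) == length(cell_types))
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (!all(cell_types %in% type_names)) {
    stop("every cell label must be one of type_names", call. = FALSE)
  }
  if (!all(type_names %in% cell_types)) {
    stop("every type in type_names needs at least one cell", call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, NULL)
  structure(
    list(counts = counts, gene_ids = gene_ids,
         cell_types = as.character(cell_types),
         type_names = as.character(type_names),
         marker_sets = marker_sets),
    class = "single_cell_dataset"
  )
}

#' Generate a synthetic cell-level dataset
#'
#' Draws counts per gene and cell from a negative binomial whose mean is the
#' per-gene baseline, elevated `marker_fold`-fold for the markers of the
#' cell's own type, and scaled by a per-cell log-normal library factor.
#' Marker blocks are disjoint and assigned to the leading genes in type
#' order, so the planted structure is recoverable in tests.
#'
#' @param spec a [single_cell_spec()].
#' @return an object of class `single_cell_dataset` with fields `counts`
#'   (genes x cells integer matrix), `gene_ids`, `cell_types`, `type_names`
#'   and `marker_sets` (list of planted marker gene ids per type).
#' @examples
#' sc <- generate_single_cell_dataset(single_cell_spec(
#'   n_genes = 200, n_cells_per_type = 20, n_types = 3, seed = 7))
#' table(sc$cell_types)
#' @export
generate_single_cell_dataset <- function(spec) {
  stopifnot(inherits(spec, "single_cell_spec"))
  K <- spec$n_types
  M <- spec$n_genes
  n_cells <- sum(spec$n_cells_per_type)
  gene_ids <- sprintf("gene_%05d", seq_len(M))
  type_names <- sprintf("type_%d", seq_len(K))
  cell_types <- rep(type_names, times = spec$n_cells_per_type)

  n_mark <- floor(spec$marker_frac * M)
  marker_sets <- vector("list", K)
  names(marker_sets) <- type_names
  for (k in seq_len(K)) {
    idx <- if (n_mark > 0) ((k - 1L) * n_mark + 1L):(k * n_mark) else integer()
    marker_sets[[k]] <- gene_ids[idx]
  }

  # fold matrix: genes x types, marker_fold on a type's own markers
  fold <- matrix(1, M, K)
  for (k in seq_len(K)) {
    fold[match(marker_sets[[k]], gene_ids), k] <- spec$marker_fold
  }

  counts <- with_seed(child_seed(spec$seed, 0L), {
    lib <- if (spec$libsize_sigma > 0) {
      exp(stats::rnorm(n_cells, -spec$libsize_sigma^2 / 2,
                       spec$libsize_sigma))
    } else {
      rep(1, n_cells)
    }
    type_idx <- match(cell_types, type_names)
    mu <- (spec$base_mean * fold[, type_idx, drop = FALSE]) *
      rep(lib, each = M)
    x <- if (spec$dispersion > 0) {
      stats::rnbinom(M * n_cells, mu = mu, size = 1 / spec$dispersion)
    } else {
      stats::rpois(M * n_cells, lambda = mu)
    }
    matrix(x, M, n_cells)
  })

  new_single_cell_dataset(counts, gene_ids, cell_types, type_names,
                          marker_sets = marker_sets)
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat(sprintf("single_cell_dataset: %d genes x %d cells, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(x$type_names)))
  tab <- table(factor(x$cell_types, levels = x$type_names))
  cat("  cells per type: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# mean profile (genes x types) of a single_cell_dataset
type_means <- function(data) {
  K <- length(data$type_names)
  out <- matrix(0, nrow(data$counts), K,
                dimnames = list(data$gene_ids, data$type_names))
  for (k in seq_len(K)) {
    cols <- data$cell_types == data$type_names[k]
    out[, k] <- rowMeans(data$counts[, cols, drop = FALSE])
  }
  out
}

#' Shrink cells toward their type mean profile
#'
#' Emulates reference data produced by a parametric simulator, which is much
#' less variable than real cells: every cell's profile is pulled toward its
#' cell-type mean by the factor `shrink` (0 = unchanged, 1 = collapse onto
#' the type mean), then re-rounded to non-negative integers with base-R
#' rounding.
#'
#' @param data a `single_cell_dataset`.
#' @param shrink shrinkage fraction in `[0, 1]`.
#' @param seed unused (the operator is deterministic); accepted so all
#'   discrepancy operators share one signature.
#' @return a `single_cell_dataset` with the same labels and genes.
#' @export
reduce_variability <- function(data, shrink, seed = NULL) {
  stopifnot(inherits(data, "single_cell_dataset"))
  stop_if_not_scalar_number(shrink, "shrink", lower = 0, upper = 1)
  if (shrink == 0) return(data)
  mu <- type_means(data)
  idx <- match(data$cell_types, data$type_names)
  target <- mu[, idx, drop = FALSE]
  newc <- data$counts + shrink * (target - data$counts)
  newc <- pmax(round(newc), 0)
  new_single_cell_dataset(newc, data$gene_ids, data$cell_types,
                          data$type_names, marker_sets = data$marker_sets)
}

#' Apply a platform shift to a cell-level dataset
#'
#' Emulates technical discrepancy between platforms (for example scRNA-seq
#' versus snRNA-seq): every gene receives one multiplicative log-normal bias
#' factor `exp(bias_sigma * z_g)` shared by all cells, and a further fraction
#' `dropout_delta` of its nonzero entries is set to zero. Zeros never become
#' nonzero. The per-gene standard normal draws `z_g` depend only on `seed`,
#' so shifts at increasing `bias_sigma` under the same seed are coupled.
#'
#' @param data a `single_cell_dataset`.
#' @param bias_sigma log-scale spread of the per-gene bias (>= 0).
#' @param dropout_delta fraction in `[0, 1)` of nonzero entries zeroed per
#'   gene.
#' @param seed integer seed.
#' @return a `single_cell_dataset`.
#' @export
platform_shift <- function(data, bias_sigma, dropout_delta = 0, seed = 1L) {
  stopifnot(inherits(data, "single_cell_dataset"))
  stop_if_not_scalar_number(bias_sigma, "bias_sigma", lower = 0)
  if (!is.numeric(dropout_delta) || length(dropout_delta) != 1L ||
      dropout_delta < 0 || dropout_delta >= 1) {
    stop("`dropout_delta` must lie in [0, 1)", call. = FALSE)
  }
  if (bias_sigma == 0 && dropout_delta == 0) return(data)
  M <- nrow(data$counts)
  newc <- with_seed(child_seed(seed, 1L), {
    z <- stats::rnorm(M)
    x <- data$counts * exp(bias_sigma * z)
    if (dropout_delta > 0) {
      nz <- which(x > 0)
      drop <- nz[stats::runif(length(nz)) < dropout_delta]
      x[drop] <- 0
    }
    x
  })
  newc <- pmax(round_half_up(newc), 0)
  new_single_cell_dataset(newc, data$gene_ids, data$cell_types,
                          data$type_names, marker_sets = data$marker_sets)
}
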