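# Ideal mixing: pseudo-bulk RNA-seq samples built by summing the raw count
# profiles of randomly sampled single cells, followed by the benchmark's gene
# filter and column normalization.

new_pseudo_bulk <- function(expression, gene_ids, sample_ids, truth, intended,
                            cells = NULL, cells_per_sample = NA_integer_,
                            normalized = FALSE) {
  stopifnot(is.matrix(expression), nrow(expression) == length(gene_ids),
            ncol(expression) == length(sample_ids))
  if (any(expression < 0) || any(!is.finite(expression))) {
    stop("expression must be non-negative and finite", call. = FALSE)
  }
  dimnames(expression) <- list(gene_ids, sample_ids)
  structure(
    list(expression = expression, gene_ids = gene_ids,
         sample_ids = sample_ids, truth = truth, intended = intended,
         cells = cells, cells_per_sample = cells_per_sample,
         normalized = normalized),
    class = "pseudo_bulk"
  )
}

#' Construct a pseudo-bulk dataset from components
#'
#' Low-level constructor, useful for building noiseless mixtures `G = C P`
#' directly in tests and examples. [ideal_mix()] is the simulation entry
#' point.
#'
#' @param expression genes x samples non-negative matrix.
#' @param truth a [proportion_matrix()] of ground-truth compositions.
#' @param gene_ids,sample_ids identifiers; defaults taken from dimnames.
#' @param intended optional [proportion_matrix()] of intended (drawn)
#'   compositions; defaults to `truth`.
#' @return an object of class `pseudo_bulk`.
#' @export
pseudo_bulk <- function(expression, truth,
                        gene_ids = rownames(expression),
                        sample_ids = colnames(expression),
                        intended = truth) {
  expression <- as.matrix(expression)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(expression)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(ncol(expression)))
  stopifnot(inherits(truth, "proportion_matrix"),
            ncol(truth$values) == ncol(expression))
  new_pseudo_bulk(expression, gene_ids, sample_ids, truth, intended)
}

#' @export
print.pseudo_bulk <- function(x, ...) {
  cat(sprintf("pseudo_bulk: %d genes x %d samples (%s)\n",
              nrow(x$expression), ncol(x$expression),
              if (isTRUE(x$normalized)) "normalized" else "raw counts"))
  invisible(x)
}

#' Build pseudo-bulk samples by ideal mixing of single cells
#'
#' For each sample j, cell-type counts are drawn from a
#' multinomial(`cells_per_sample`, P[, j]); for each type, that many cells
#' are sampled with replacement from the type's pool; their raw count
#' vectors are summed into column j. The realized ground truth is the vector
#' of multinomial counts divided by `cells_per_sample` (the exact composition
#' of the constructed sample); the Dirichlet draw is kept as the `intended`
#' composition.
#'
#' @param data a `single_cell_dataset` supplying the cell pool.
#' @param P a [proportion_matrix()] of intended compositions; its types must
#'   all be present in `data`.
#' @param cells_per_sample number of cells summed per sample.
#' @param seed integer seed.
#' @return a `pseudo_bulk` object carrying `truth` (realized), `intended`,
#'   and the list of sampled cell indices per sample (`cells`), so column
#'   totals can be audited against the constituent cells.
#' @export
ideal_mix <- function(data, P, cells_per_sample = 500, seed = 1L) {
  stopifnot(inherits(data, "single_cell_dataset"),
            inherits(P, "proportion_matrix"))
  stop_if_not_scalar_number(cells_per_sample, "cells_per_sample", lower = 1)
  if (!all(P$type_names %in% data$type_names)) {
    stop("P contains types absent from the cell-level data", call. = FALSE)
  }
  pos <- rowSums(P$values) > 0
  have_cells <- P$type_names %in% unique(data$cell_types)
  if (any(pos & !have_cells)) {
    stop("a type with positive proportion has no cells in the data",
         call. = FALSE)
  }
  n <- ncol(P$values)
  if (n < 1) stop("P is empty", call. = FALSE)
  K <- length(P$type_names)
  pools <- lapply(P$type_names, function(tn) which(data$cell_types == tn))

  M <- nrow(data$counts)
  expr <- matrix(0, M, n)
  truth <- matrix(0, K, n)
  cells <- vector("list", n)
  with_seed(child_seed(seed, 3L), {
    for (j in seq_len(n)) {
      nk <- as.integer(stats::rmultinom(1, cells_per_sample, P$values[, j]))
      truth[, j] <- nk / cells_per_sample
      idx <- integer(0)
      for (k in seq_len(K)) {
        if (nk[k] > 0) {
          idx <- c(idx, sample(pools[[k]], nk[k], replace = TRUE))
        }
      }
      cells[[j]] <- idx
      expr[, j] <- rowSums(data$counts[, idx, drop = FALSE])
    }
  })
  sample_ids <- colnames(P$values)
  truth_pm <- proportion_matrix(truth, P$type_names)
  colnames(truth_pm$values) <- sample_ids
  new_pseudo_bulk(expr, data$gene_ids, sample_ids, truth_pm, P,
                  cells = cells,
                  cells_per_sample = as.integer(cells_per_sample))
}

#' Remove lowly expressed genes from a pseudo-bulk dataset
#'
#' A gene is discarded iff it has fewer than `min_count` reads in at least
#' `sample_frac` of the samples. Gene order is otherwise preserved and the
#' filter is idempotent.
#'
#' @param bulk a `pseudo_bulk` object.
#' @param min_count count threshold (default 10).
#' @param sample_frac fraction-of-samples threshold (default 0.8).
#' @return the filtered `pseudo_bulk`.
#' @export
filter_genes <- function(bulk, min_count = 10, sample_frac = 0.8) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  n <- ncol(bulk$expression)
  n_below <- rowSums(bulk$expression < min_count)
  drop <- n_below >= sample_frac * n - 1e-9
  if (all(drop)) stop("gene filter removed all genes", call. = FALSE)
  bulk$expression <- bulk$expression[!drop, , drop = FALSE]
  bulk$gene_ids <- bulk$gene_ids[!drop]
  bulk
}

#' Rescale every pseudo-bulk column to a common total
#'
#' Column normalization in the counts-per-million convention: each sample's
#' column is rescaled to sum to `scale`.
#'
#' @param bulk a `pseudo_bulk` object; every column must have a positive
#'   total.
#' @param scale target column total (default 1e6).
#' @return the normalized `pseudo_bulk`.
#' @export
column_normalize <- function(bulk, scale = 1e6) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  stop_if_not_scalar_number(scale, "scale", lower = 0, strict_lower = TRUE)
  tot <- colSums(bulk$expression)
  if (any(tot <= 0)) stop("zero-total column cannot be normalized",
                          call. = FALSE)
  bulk$expression <- sweep(bulk$expression, 2, tot / scale, "/")
  bulk$normalized <- TRUE
  bulk
}

#' Diagnostic residual profile of ideal mixing
#'
#' Compares each pseudo-bulk column with its expectation under the mixing
#' model, `C_raw %*% (truth * cells_per_sample)`, where `C_raw` holds the
#' per-type mean raw cell profiles. The residual has mean zero over
#' replicates; the summary is diagnostic only.
#'
#' @param bulk a raw (unnormalized) `pseudo_bulk` produced by [ideal_mix()].
#' @param data the generating `single_cell_dataset`.
#' @return a data.frame with per-gene mean residual and residual SD across
#'   samples.
#' @export
mixing_noise_profile <- function(bulk, data) {
  stopifnot(inherits(bulk, "pseudo_bulk"),
            inherits(data, "single_cell_dataset"))
  if (!identical(bulk$gene_ids, data$gene_ids)) {
    stop("bulk and data gene sets differ (was the bulk filtered?)",
         call. = FALSE)
  }
  mu <- type_means(data)[, bulk$truth$type_names, drop = FALSE]
  expected <- mu %*% (bulk$truth$values * bulk$cells_per_sample)
  resid <- bulk$expression - expected
  data.frame(gene_id = bulk$gene_ids,
             mean_residual = rowMeans(resid),
             sd_residual = apply(resid, 1, stats::sd),
             row.names = NULL)
}
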