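# The three controlled manipulations applied to the bulk-generating copy of
# the cell-level data in the resilience experiments. The reference copy is
# left pristine; the resulting mismatch between bulk and reference is what
# the resilience analysis measures.

#' Shift expression upward by a fraction of the type mean
#'
#' For every gene and every cell, adds `fraction` times the gene's average
#' expression within the cell's own type, then rounds half-up to keep counts
#' integer. The benchmark grid uses fractions 0.1, 0.3, 0.5 and 0.7.
#'
#' @param data a `single_cell_dataset`.
#' @param fraction non-negative shift fraction; 0 is the identity.
#' @return a `single_cell_dataset` with unchanged labels and genes.
#' @export
mean_shift <- function(data, fraction) {
  stopifnot(inherits(data, "single_cell_dataset"))
  stop_if_not_scalar_number(fraction, "fraction", lower = 0)
  if (fraction == 0) return(data)
  mu <- type_means(data)
  idx <- match(data$cell_types, data$type_names)
  newc <- data$counts + fraction * mu[, idx, drop = FALSE]
  newc <- pmax(round_half_up(newc), 0)
  new_single_cell_dataset(newc, data$gene_ids, data$cell_types,
                          data$type_names, marker_sets = data$marker_sets)
}

#' Remove the most or least expressed cells of each type
#'
#' Within each cell type, cells are ranked by their total counts and
#' `floor(q * n_k)` cells are removed from the stated extreme (`side`).
#' Remaining cells keep their original order. Each type always retains at
#' least one cell; `q = 0` is the identity.
#'
#' @param data a `single_cell_dataset`.
#' @param side `"top"` removes the most expressed cells, `"bottom"` the
#'   least expressed.
#' @param q truncation fraction in `[0, 0.5]` (default 0.1).
#' @return a `single_cell_dataset` with fewer cells.
#' @export
truncate_cells <- function(data, side = c("top", "bottom"), q = 0.1) {
  stopifnot(inherits(data, "single_cell_dataset"))
  side <- match.arg(side)
  stop_if_not_scalar_number(q, "q", lower = 0, upper = 0.5)
  if (q == 0) return(data)
  totals <- colSums(data$counts)
  keep <- rep(TRUE, ncol(data$counts))
  for (tn in data$type_names) {
    cells_k <- which(data$cell_types == tn)
    n_remove <- floor(q * length(cells_k))
    if (n_remove >= length(cells_k)) {
      stop(sprintf("truncation would empty type '%s'", tn), call. = FALSE)
    }
    if (n_remove == 0) next
    # rank by total counts, ties broken by original cell order
    ord <- cells_k[order(totals[cells_k], seq_along(cells_k))]
    victims <- if (side == "top") {
      ord[(length(ord) - n_remove + 1):length(ord)]
    } else {
      ord[seq_len(n_remove)]
    }
    keep[victims] <- FALSE
  }
  new_single_cell_dataset(data$counts[, keep, drop = FALSE], data$gene_ids,
                          data$cell_types[keep], data$type_names,
                          marker_sets = data$marker_sets)
}

#' Multiply all expression values by a global factor
#'
#' Every entry is multiplied by `factor` and rounded half-up to a
#' non-negative integer. The benchmark grid uses factors 0.4, 0.8, 1.2 and
#' 1.8. Because pseudo-bulk columns are later rescaled to a common total,
#' global factoring is absorbed by the normalization up to rounding error.
#'
#' @param data a `single_cell_dataset`.
#' @param factor positive scaling factor; 1 is the identity.
#' @param per_type optional named numeric vector of per-type factors
#'   overriding `factor` (an interpretation switch; the default applies one
#'   global factor).
#' @return a `single_cell_dataset`.
#' @export
scale_expression <- function(data, factor, per_type = NULL) {
  stopifnot(inherits(data, "single_cell_dataset"))
  stop_if_not_scalar_number(factor, "factor", lower = 0, strict_lower = TRUE)
  if (is.null(per_type)) {
    if (factor == 1) return(data)
    newc <- data$counts * factor
  } else {
    if (!all(data$type_names %in% names(per_type))) {
      stop("per_type must name every cell type", call. = FALSE)
    }
    if (any(per_type <= 0)) stop("per-type factors must be positive",
                                 call. = FALSE)
    f <- per_type[data$cell_types]
    newc <- sweep(data$counts, 2, f, "*")
  }
  newc <- pmax(round_half_up(newc), 0)
  new_single_cell_dataset(newc, data$gene_ids, data$cell_types,
                          data$type_names, marker_sets = data$marker_sets)
}

#' Benchmark perturbation grids
#'
#' Returns the preset list of perturbation specifications for one
#' manipulation family: mean shifting over fractions 0.1/0.3/0.5/0.7,
#' truncation of the top or bottom 10% of cells, or global factoring over
#' 0.4/0.8/1.2/1.8.
#'
#' @param kind one of `"mean_shift"`, `"truncate"`, `"factor"`.
#' @return a list of perturbation specs consumable by
#'   [apply_perturbation()]; each has a `label` field.
#' @export
perturbation_grid <- function(kind = c("mean_shift", "truncate", "factor")) {
  kind <- match.arg(kind)
  switch(kind,
    mean_shift = lapply(c(0.1, 0.3, 0.5, 0.7), function(f) {
      list(kind = "mean_shift", fraction = f,
           label = sprintf("mean_shift_%g", f))
    }),
    truncate = lapply(c("top", "bottom"), function(s) {
      list(kind = "truncate", side = s, q = 0.1,
           label = sprintf("truncate_%s_0.1", s))
    }),
    factor = lapply(c(0.4, 0.8, 1.2, 1.8), function(f) {
      list(kind = "factor", factor = f, label = sprintf("factor_%g", f))
    })
  )
}

#' Apply one perturbation specification
#'
#' Dispatches a spec produced by [perturbation_grid()] (or hand-written with
#' the same fields) to [mean_shift()], [truncate_cells()] or
#' [scale_expression()]. Perturbations are not composed implicitly; apply
#' them in sequence if a combination is wanted.
#'
#' @param data a `single_cell_dataset`.
#' @param spec a list with a `kind` field plus the operator's parameters.
#' @return a `single_cell_dataset`.
#' @export
apply_perturbation <- function(data, spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
    mean_shift = mean_shift(data, spec$fraction),
    truncate = truncate_cells(data, spec$side %||% "top", spec$q %||% 0.1),
    factor = scale_expression(data, spec$factor, spec$per_type %||% NULL),
    stop(sprintf("unknown perturbation kind '%s'", spec$kind), call. = FALSE)
  )
}
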