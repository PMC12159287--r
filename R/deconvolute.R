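# Front-end estimator: one fitting function dispatching to the five solver
# families, returning a classed fit with the usual accessor methods.

#' Estimate cell-type proportions of pseudo-bulk samples
#'
#' Central fitting function of the package. Reference-based methods
#' (`"nnls"`, `"wnnls"`, `"nusvr"`) require a signature matrix or a labelled
#' cell-level reference; reference-free methods (`"simplex"`, `"nmf"`) read
#' only the bulk matrix and return anonymous components, which can be
#' aligned to a ground truth with [match_components()] (done automatically
#' when `truth` is supplied).
#'
#' @param bulk a `pseudo_bulk` object (typically filtered and normalized).
#' @param method one of `"nnls"`, `"wnnls"`, `"nusvr"`, `"simplex"`,
#'   `"nmf"`.
#' @param signature a [signature_matrix()] (for `"nnls"` / `"nusvr"`; built
#'   from `reference` when missing).
#' @param reference a `single_cell_dataset` (required for `"wnnls"`, usable
#'   to build the signature for the other reference-based methods).
#' @param K number of cell types for the reference-free methods; defaults to
#'   the truth/reference when available.
#' @param truth optional [proportion_matrix()]; when given, reference-free
#'   components are matched to it.
#' @param seed integer seed used by the seeded solvers (`"simplex"`,
#'   `"nmf"`).
#' @param ... passed on to the underlying solver (for example `n_iter`,
#'   `nu_grid`, `n_markers_per_type`, or a full `nmf_config` via `cfg`).
#' @return an object of class `deconv_fit` with `proportions` (a
#'   [proportion_matrix()]), per-sample `diagnostics`, and solver `details`.
#' @examples
#' sc <- generate_single_cell_dataset(single_cell_spec(
#'   n_genes = 300, n_cells_per_type = 30, n_types = 3, seed = 1))
#' P <- sample_proportions(dirichlet_spec(c(2, 1, 1), 12, seed = 2))
#' bulk <- column_normalize(filter_genes(ideal_mix(sc, P, 100, seed = 3)))
#' fit <- deconvolute(bulk, "nnls", reference = sc)
#' head(t(coef(fit)))
#' @export
deconvolute <- function(bulk, method = c("nnls", "wnnls", "nusvr", "simplex",
                                         "nmf"),
                        signature = NULL, reference = NULL, K = NULL,
                        truth = NULL, seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(bulk, "pseudo_bulk"))
  if (method %in% c("nnls", "nusvr") && is.null(signature)) {
    if (is.null(reference)) {
      stop(sprintf("method '%s' needs a signature or a reference", method),
           call. = FALSE)
    }
    signature <- build_signature(reference)
  }
  if (method %in% c("simplex", "nmf") && is.null(K)) {
    K <- if (!is.null(truth)) {
      nrow(as_prop_values(truth))
    } else if (!is.null(reference)) {
      length(reference$type_names)
    } else {
      stop("reference-free methods need K (or a truth/reference to infer it)",
           call. = FALSE)
    }
  }
  fit <- switch(method,
    nnls = nnls_deconv(bulk, signature),
    wnnls = {
      if (is.null(reference)) stop("method 'wnnls' needs a reference",
                                   call. = FALSE)
      wnnls_deconv(bulk, reference, ...)
    },
    nusvr = nusvr_deconv(bulk, signature, ...),
    simplex = {
      est <- simplex_deconv(bulk, K, seed = seed)
      if (!is.null(truth)) {
        match_components(est, truth, method = "simplex")
      } else {
        new_deconv_fit(est, "simplex",
                       data.frame(sample_id = bulk$sample_ids),
                       details = list(corner_genes = attr(est,
                                                          "corner_genes")))
      }
    },
    nmf = {
      dots <- list(...)
      cfg <- dots$cfg %||% nmf_config(K = K, lambda1 = 1, lambda2 = 0.1,
                                      seed = seed)
      res <- nmf_marker_deconv(bulk, cfg)
      if (!is.null(truth)) {
        fit <- match_components(res$proportions, truth, method = "nmf")
        fit$details$signature <- res$signature
        fit$details$objective <- res$objective
        fit$details$converged <- res$converged
        fit
      } else {
        new_deconv_fit(res$proportions, "nmf",
                       data.frame(sample_id = bulk$sample_ids),
                       details = list(signature = res$signature,
                                      objective = res$objective,
                                      converged = res$converged))
      }
    }
  )
  fit$details$truth <- truth
  fit
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("deconv_fit (%s): %d types x %d samples\n", x$method,
              nrow(x$proportions$values), ncol(x$proportions$values)))
  cat("  mean estimated composition:",
      paste(sprintf("%s=%.3f", x$proportions$type_names,
                    rowMeans(x$proportions$values)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.deconv_fit <- function(object, ...) {
  out <- list(method = object$method,
              proportions = object$proportions,
              diagnostics = object$diagnostics)
  if (!is.null(object$details$truth)) {
    out$metrics <- evaluate_deconv(object$details$truth, object)
  }
  class(out) <- "summary.deconv_fit"
  out
}

#' @export
print.summary.deconv_fit <- function(x, ...) {
  cat(sprintf("Deconvolution by '%s'\n", x$method))
  print(x$proportions)
  if (!is.null(x$metrics)) {
    cat(sprintf("  vs truth: R = %.4f, RMSD = %.4f, MAD = %.4f\n",
                x$metrics$pearson_r, x$metrics$rmsd, x$metrics$mad))
  }
  invisible(x)
}

#' @export
coef.deconv_fit <- function(object, ...) {
  object$proportions$values
}

#' @export
fitted.deconv_fit <- function(object, ...) {
  object$fitted
}

#' @export
residuals.deconv_fit <- function(object, ...) {
  if (is.null(object$fitted) || is.null(object$observed)) return(NULL)
  object$observed - object$fitted
}

#' Plot estimated against true proportions
#'
#' Scatter of all entries of the estimated composition matrix against the
#' ground truth, one color per cell type, with the identity line.
#'
#' @param x a `deconv_fit`.
#' @param truth a [proportion_matrix()]; defaults to the truth stored at fit
#'   time.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deconv_fit <- function(x, truth = NULL, ...) {
  truth <- truth %||% x$details$truth
  if (is.null(truth)) stop("no ground truth available to plot against",
                           call. = FALSE)
  tv <- as_prop_values(truth)
  ev <- x$proportions$values
  K <- nrow(tv)
  cols <- grDevices::hcl.colors(K, "Dark 3")
  graphics::plot(as.vector(tv), as.vector(ev),
                 col = rep(cols, ncol(tv)),
                 xlab = "true proportion", ylab = "estimated proportion",
                 main = sprintf("%s (R = %.3f)", x$method,
                                pearson_r(truth, x)), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = rownames(tv), col = cols, pch = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
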