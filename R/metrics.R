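# The three evaluation metrics comparing estimated to true compositions:
# Pearson's correlation R = Cor(p, p_hat), the per-sample root mean squared
# deviation RMSD = sqrt(sum_k (p_k - p_hat_k)^2 / K), and the per-sample mean
# absolute deviation MAD = (1/K) sum_k |p_k - p_hat_k|. RMSD and MAD are
# averaged over samples; by the power-mean inequality MAD <= RMSD holds per
# sample and after averaging.

as_prop_values <- function(x) {
  if (inherits(x, "proportion_matrix")) return(x$values)
  if (inherits(x, "deconv_fit")) return(x$proportions$values)
  as.matrix(x)
}

check_shapes <- function(truth, est) {
  if (!all(dim(truth) == dim(est))) {
    stop("truth and estimate shapes differ", call. = FALSE)
  }
}

#' Pearson correlation between true and estimated proportions
#'
#' In `pooled` mode (the default, matching one reported R per scenario) both
#' K x n matrices are flattened and a single correlation is returned; in
#' `per_sample` mode the mean of per-column correlations is returned.
#'
#' @param truth,est proportion matrices ([proportion_matrix()],
#'   `deconv_fit`, or plain K x n matrices) of matching shape.
#' @param mode `"pooled"` or `"per_sample"`.
#' @return a single correlation.
#' @export
pearson_r <- function(truth, est, mode = c("pooled", "per_sample")) {
  mode <- match.arg(mode)
  truth <- as_prop_values(truth)
  est <- as_prop_values(est)
  check_shapes(truth, est)
  if (mode == "pooled") {
    x <- as.vector(truth)
    y <- as.vector(est)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in flattened proportions", call. = FALSE)
    }
    stats::cor(x, y)
  } else {
    rs <- vapply(seq_len(ncol(truth)), function(j) {
      x <- truth[, j]
      y <- est[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop(sprintf("zero variance in sample %d", j), call. = FALSE)
      }
      stats::cor(x, y)
    }, numeric(1))
    mean(rs)
  }
}

#' Root mean squared deviation of estimated proportions
#'
#' Computes `sqrt(sum_k (p_k - p_hat_k)^2 / K)` per sample and averages over
#' samples.
#'
#' @inheritParams pearson_r
#' @param aggregate how per-sample values are combined (only
#'   `"mean_over_samples"`).
#' @return a single non-negative value.
#' @export
rmsd <- function(truth, est, aggregate = "mean_over_samples") {
  stopifnot(identical(aggregate, "mean_over_samples"))
  truth <- as_prop_values(truth)
  est <- as_prop_values(est)
  check_shapes(truth, est)
  per_sample <- sqrt(colMeans((truth - est)^2))
  mean(per_sample)
}

#' Mean absolute deviation of estimated proportions
#'
#' Computes `(1/K) sum_k |p_k - p_hat_k|` per sample and averages over
#' samples. Per sample (and in aggregate) MAD <= RMSD.
#'
#' @inheritParams rmsd
#' @return a single non-negative value.
#' @export
mad <- function(truth, est, aggregate = "mean_over_samples") {
  stopifnot(identical(aggregate, "mean_over_samples"))
  truth <- as_prop_values(truth)
  est <- as_prop_values(est)
  check_shapes(truth, est)
  mean(colMeans(abs(truth - est)))
}

#' Score an estimate with all three metrics
#'
#' @inheritParams pearson_r
#' @param mode correlation mode passed to [pearson_r()].
#' @return a one-row data.frame with columns `pearson_r`, `rmsd`, `mad` and
#'   `n_samples`.
#' @export
evaluate_deconv <- function(truth, est, mode = "pooled") {
  tv <- as_prop_values(truth)
  data.frame(pearson_r = pearson_r(truth, est, mode),
             rmsd = rmsd(truth, est),
             mad = mad(truth, est),
             n_samples = ncol(tv))
}
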