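# Orchestration: a declarative scenario configuration drives the full
# generate -> (perturb / shift) -> sample proportions -> ideal mix -> filter /
# normalize -> deconvolve -> score pipeline, one metric-report row per
# (tier, method). All stage seeds derive from one master seed.

#' Build a scenario configuration
#'
#' A scenario fixes the cell-level generator, the Dirichlet composition
#' model (a named tissue preset or a custom concentration vector) with one
#' or more variation tiers, the mixing parameters, the discrepancies between
#' the bulk-generating and reference copies, the methods to run and the
#' metric mode.
#'
#' Discrepancy semantics: `perturbations` and `reduce_variability` act on
#' the bulk-generating copy (the reference stays pristine, as in the
#' manipulation and synthetic-generator experiments); `platform_shift` acts
#' on the reference copy (the platform-difference experiment, where the
#' reference comes from another technology). Reference-free methods never
#' read the reference copy.
#'
#' @param name scenario identifier.
#' @param sc_spec a [single_cell_spec()] (its `n_types` must match the
#'   length of the concentration vector).
#' @param tissue tissue preset name passed to [dirichlet_preset()], or
#'   `NULL` when `p` is given.
#' @param p custom concentration vector (overrides `tissue`).
#' @param tiers character vector among `"small"`, `"medium"`, `"large"`;
#'   custom `p` is divided by 1/10/100 accordingly.
#' @param n_samples pseudo-bulk samples per tier (default 50).
#' @param cells_per_sample cells summed per sample (default 500).
#' @param methods methods to run, a subset of
#'   `c("nnls", "wnnls", "nusvr", "simplex", "nmf")`.
#' @param perturbation optional perturbation spec (see
#'   [apply_perturbation()]) applied to the bulk-generating copy.
#' @param reduce_variability optional shrink fraction in `[0, 1]` applied to
#'   the bulk-generating copy.
#' @param platform_shift optional list with `bias_sigma` and optional
#'   `dropout_delta`, applied to the reference copy.
#' @param ground_truth `"realized"` (multinomial fractions; default) or
#'   `"intended"` (Dirichlet draws) as the evaluation truth.
#' @param metric_mode correlation mode, `"pooled"` or `"per_sample"`.
#' @param n_markers_per_type signature size per type for reference-based
#'   methods.
#' @param min_count,sample_frac gene-filter parameters (defaults 10, 0.8).
#' @param out_dir optional directory; when set, [run_scenario()] writes all
#'   intermediate artifacts there.
#' @param seed master seed; every stage derives its own child seed from it.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = "scenario",
                            sc_spec = single_cell_spec(),
                            tissue = "pancreas", p = NULL,
                            tiers = c("small", "medium", "large"),
                            n_samples = 50, cells_per_sample = 500,
                            methods = c("nnls", "wnnls", "nusvr", "simplex",
                                        "nmf"),
                            perturbation = NULL,
                            reduce_variability = NULL,
                            platform_shift = NULL,
                            ground_truth = c("realized", "intended"),
                            metric_mode = c("pooled", "per_sample"),
                            n_markers_per_type = 50,
                            min_count = 10, sample_frac = 0.8,
                            out_dir = NULL, seed = 1L) {
  stopifnot(inherits(sc_spec, "single_cell_spec"))
  ground_truth <- match.arg(ground_truth)
  metric_mode <- match.arg(metric_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0) stop("methods must be non-empty", call. = FALSE)
  tiers <- match.arg(tiers, c("small", "medium", "large"), several.ok = TRUE)
  if (is.null(p)) {
    if (is.null(tissue)) stop("give either a tissue preset or p",
                              call. = FALSE)
    base_p <- dirichlet_preset(tissue, "small")$p
  } else {
    base_p <- p
    if (is.null(names(base_p))) {
      names(base_p) <- sprintf("type_%d", seq_along(base_p))
    }
  }
  if (length(base_p) != sc_spec$n_types) {
    stop("concentration vector length must equal sc_spec$n_types",
         call. = FALSE)
  }
  if (is.null(seed)) stop("a master seed must be set", call. = FALSE)
  structure(
    list(name = name, sc_spec = sc_spec, tissue = tissue, p = base_p,
         tiers = tiers, n_samples = as.integer(n_samples),
         cells_per_sample = as.integer(cells_per_sample), methods = methods,
         perturbation = perturbation,
         reduce_variability = reduce_variability,
         platform_shift = platform_shift, ground_truth = ground_truth,
         metric_mode = metric_mode,
         n_markers_per_type = as.integer(n_markers_per_type),
         min_count = min_count, sample_frac = sample_frac,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

tier_divisor <- c(small = 1, medium = 10, large = 100)

reference_based <- c("nnls", "wnnls", "nusvr")

#' Run one benchmarking scenario
#'
#' Executes the full pipeline described by the configuration and returns a
#' tidy metric report with one row per (tier, method). Rerunning the same
#' configuration yields an identical report. When `cfg$out_dir` is set,
#' intermediate artifacts (cell-level data, proportions, pseudo-bulk,
#' estimates, report) are written there, stamped with the configuration hash
#' and master seed.
#'
#' @param cfg a [scenario_config()].
#' @return a data.frame of class `metric_report` with columns `scenario`,
#'   `method`, `variation_tier`, `perturbation`, `pearson_r`, `rmsd`, `mad`,
#'   `n_samples`, `seed`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  stamp <- sprintf("config_hash=%s seed=%d",
                   config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
                   cfg$seed)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s | stage %s] %s", cfg$name, what,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sc_spec <- cfg$sc_spec
  sc_spec$seed <- child_seed(cfg$seed, 10L)
  reference <- stage("generate", generate_single_cell_dataset(sc_spec))

  bulk_source <- reference
  perturb_label <- "none"
  if (!is.null(cfg$reduce_variability)) {
    bulk_source <- stage("reduce_variability",
                         reduce_variability(bulk_source,
                                            cfg$reduce_variability))
    perturb_label <- sprintf("reduce_var_%g", cfg$reduce_variability)
  }
  if (!is.null(cfg$perturbation)) {
    bulk_source <- stage("perturb",
                         apply_perturbation(bulk_source, cfg$perturbation))
    perturb_label <- cfg$perturbation$label %||% cfg$perturbation$kind
  }
  if (!is.null(cfg$platform_shift)) {
    ps <- cfg$platform_shift
    reference <- stage("platform_shift",
                       platform_shift(reference, ps$bias_sigma,
                                      ps$dropout_delta %||% 0,
                                      seed = child_seed(cfg$seed, 11L)))
    perturb_label <- paste0(perturb_label, sprintf("+ref_shift_%g",
                                                   ps$bias_sigma))
  }

  if (!is.null(out)) {
    write_single_cell(bulk_source, file.path(out, "bulk_source"),
                      comment = stamp)
  }

  needs_sig <- any(cfg$methods %in% c("nnls", "nusvr"))
  sig <- if (needs_sig) {
    stage("signature", build_signature(reference, cfg$n_markers_per_type))
  } else {
    NULL
  }
  if (!is.null(sig) && !is.null(out)) {
    write_signature(sig, file.path(out, "signature.tsv"), comment = stamp)
  }

  rows <- list()
  warn_notes <- character(0)
  for (ti in seq_along(cfg$tiers)) {
    tier <- cfg$tiers[ti]
    p_tier <- cfg$p / tier_divisor[[tier]]
    dspec <- dirichlet_spec(p_tier, cfg$n_samples,
                            seed = child_seed(cfg$seed, 20L + ti),
                            type_names = names(cfg$p))
    P <- stage(paste0("proportions/", tier), sample_proportions(dspec))
    # the generator labels types type_1..K; map preset names onto them
    P_mix <- P
    P_mix$type_names <- bulk_source$type_names[seq_along(P$type_names)]
    rownames(P_mix$values) <- P_mix$type_names
    bulk <- stage(paste0("mix/", tier),
                  ideal_mix(bulk_source, P_mix, cfg$cells_per_sample,
                            seed = child_seed(cfg$seed, 30L + ti)))
    bulk <- stage(paste0("filter/", tier),
                  filter_genes(bulk, cfg$min_count, cfg$sample_frac))
    bulk <- stage(paste0("normalize/", tier), column_normalize(bulk))
    truth <- if (cfg$ground_truth == "realized") bulk$truth else bulk$intended

    if (!is.null(out)) {
      write_pseudobulk(bulk, file.path(out, sprintf("bulk_%s", tier)),
                       comment = stamp)
    }

    for (m in cfg$methods) {
      fit <- withCallingHandlers(
        stage(paste0(m, "/", tier),
              deconvolute(bulk, m, signature = sig, reference = reference,
                          K = length(cfg$p), truth = truth,
                          seed = child_seed(cfg$seed, 40L + ti))),
        warning = function(w) {
          warn_notes <<- c(warn_notes, sprintf("%s/%s: %s", m, tier,
                                               conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!is.null(out)) {
        write_proportions(fit$proportions,
                          file.path(out, sprintf("estimate_%s_%s.tsv",
                                                 m, tier)),
                          comment = stamp)
      }
      met <- evaluate_deconv(truth, fit, mode = cfg$metric_mode)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = cfg$name, method = m, variation_tier = tier,
        perturbation = perturb_label, pearson_r = met$pearson_r,
        rmsd = met$rmsd, mad = met$mad, n_samples = met$n_samples,
        seed = cfg$seed)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("metric_report", "data.frame")
  attr(report, "warnings") <- warn_notes
  if (!is.null(out)) {
    write_metric_report(report, file.path(out, "metrics.tsv"),
                        comment = stamp)
  }
  report
}

#' Run a suite of scenarios and summarize trends
#'
#' Accepts a list of [scenario_config()] objects or a directory of YAML
#' configuration files (see [read_scenario_config()]), runs each scenario
#' and concatenates the reports. A per-tier summary contrasting
#' reference-based and reference-free methods is attached as attribute
#' `"summary"`.
#'
#' @param configs list of configs, or a directory path containing
#'   `*.yaml`/`*.yml` files.
#' @return a concatenated `metric_report`; scenario names must be unique.
#' @export
run_benchmark_suite <- function(configs) {
  if (is.character(configs) && length(configs) == 1 &&
      dir.exists(configs)) {
    files <- list.files(configs, pattern = "\\.ya?ml$", full.names = TRUE)
    configs <- lapply(files, read_scenario_config)
  }
  if (length(configs) == 0) stop("no configurations given", call. = FALSE)
  names_ <- vapply(configs, function(cfg) cfg$name, character(1))
  if (anyDuplicated(names_)) stop("duplicate scenario ids", call. = FALSE)
  reports <- lapply(configs, run_scenario)
  report <- do.call(rbind, reports)
  class(report) <- c("metric_report", "data.frame")
  ref <- report$method %in% reference_based
  summary_tab <- stats::aggregate(
    report$pearson_r,
    by = list(variation_tier = report$variation_tier,
              family = ifelse(ref, "reference_based", "reference_free")),
    FUN = mean)
  names(summary_tab)[3] <- "mean_pearson_r"
  attr(report, "summary") <- summary_tab
  report
}

#' Read a scenario configuration from YAML
#'
#' The YAML file mirrors the arguments of [scenario_config()]; the
#' `sc_spec` block holds the [single_cell_spec()] fields.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(single_cell_spec, y$sc_spec %||% list())
  args <- y[setdiff(names(y), "sc_spec")]
  args$sc_spec <- sc
  if (!is.null(args$p)) args$p <- unlist(args$p)
  if (!is.null(args$tiers)) args$tiers <- unlist(args$tiers)
  if (!is.null(args$methods)) args$methods <- unlist(args$methods)
  do.call(scenario_config, args)
}
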