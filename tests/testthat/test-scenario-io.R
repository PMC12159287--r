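fast_cfg <- function(name = "t", seed = 11, ...) {
  args <- list(
    name = name,
    sc_spec = single_cell_spec(n_genes = 250, n_cells_per_type = 25,
                               n_types = 3, marker_frac = 0.06,
                               base_mean = 5, seed = 1),
    tissue = "mixture", tiers = "medium", n_samples = 12,
    cells_per_sample = 80, methods = c("nnls", "simplex"), seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

test_that("run_scenario is reproducible and schema-stable", {
  cfg <- fast_cfg()
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  attr(r1, "warnings") <- attr(r2, "warnings") <- NULL
  expect_identical(r1, r2)
  expect_identical(names(r1), c("scenario", "method", "variation_tier",
                                "perturbation", "pearson_r", "rmsd", "mad",
                                "n_samples", "seed"))
  expect_equal(nrow(r1), 2) # one row per (tier, method)
  expect_true(all(r1$rmsd >= r1$mad))
})

test_that("scenario artifacts are written with a provenance stamp", {
  out <- file.path(tempdir(), "dbench_scenario")
  unlink(out, recursive = TRUE)
  cfg <- fast_cfg(out_dir = out)
  rep <- run_scenario(cfg)
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "bulk_medium_expression.tsv")))
  first <- readLines(file.path(out, "metrics.tsv"), n = 1)
  expect_match(first, "^# config_hash=[0-9a-f]+ seed=11$")
  rt <- read_metric_report(file.path(out, "metrics.tsv"))
  expect_equal(rt$pearson_r, rep$pearson_r, tolerance = 1e-9)
  unlink(out, recursive = TRUE)
})

test_that("benchmark suites concatenate reports and reject duplicate ids", {
  cfgs <- list(fast_cfg("a", seed = 1), fast_cfg("b", seed = 2))
  suite <- run_benchmark_suite(cfgs)
  expect_equal(nrow(suite), 4)
  expect_setequal(unique(suite$scenario), c("a", "b"))
  summ <- attr(suite, "summary")
  expect_true(all(c("variation_tier", "family", "mean_pearson_r") %in%
                    names(summ)))
  expect_error(run_benchmark_suite(list(fast_cfg("a"), fast_cfg("a"))),
               "duplicate")
  expect_error(run_benchmark_suite(list()), "no config")
})

test_that("four tissue designs by three tiers give 12 rows per method", {
  k_of <- c(mixture = 3, blood = 6, pancreas = 4, brain = 5)
  cfgs <- lapply(names(k_of), function(tissue) {
    scenario_config(
      name = tissue,
      sc_spec = single_cell_spec(n_genes = 240, n_cells_per_type = 15,
                                 n_types = k_of[[tissue]],
                                 marker_frac = 0.15 / k_of[[tissue]],
                                 seed = 1),
      tissue = tissue, tiers = c("small", "medium", "large"),
      n_samples = 8, cells_per_sample = 60, methods = "nnls", seed = 3)
  })
  suite <- run_benchmark_suite(cfgs)
  expect_equal(nrow(suite), 12)
  expect_equal(nrow(unique(suite[, c("scenario", "variation_tier")])), 12)
})

test_that("perturbation grids emit one report row per perturbation and method", {
  grid <- c(perturbation_grid("mean_shift"), perturbation_grid("factor"))
  cfgs <- lapply(grid, function(pt) {
    scenario_config(
      name = paste0("pert_", pt$label),
      sc_spec = single_cell_spec(n_genes = 200, n_cells_per_type = 20,
                                 n_types = 3, marker_frac = 0.06, seed = 1),
      tissue = "mixture", tiers = "medium", n_samples = 8,
      cells_per_sample = 60, methods = c("nnls", "simplex"),
      perturbation = pt, seed = 5)
  })
  suite <- run_benchmark_suite(cfgs)
  expect_equal(nrow(suite), length(grid) * 2)
  expect_setequal(unique(suite$perturbation),
                  vapply(grid, `[[`, character(1), "label"))
})

test_that("YAML scenario configs round-trip through the reader", {
  path <- file.path(tempdir(), "cfg.yaml")
  writeLines(c(
    "name: yaml_case",
    "tissue: pancreas",
    "tiers: [small, medium]",
    "n_samples: 8",
    "cells_per_sample: 60",
    "methods: [nnls]",
    "seed: 7",
    "sc_spec:",
    "  n_genes: 200",
    "  n_cells_per_type: 20",
    "  n_types: 4",
    "  seed: 3"), path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$tiers, c("small", "medium"))
  expect_equal(cfg$sc_spec$n_genes, 200L)
  rep <- run_scenario(cfg)
  expect_equal(nrow(rep), 2)
  unlink(path)
})

test_that("matrix and dataset writers round-trip", {
  dir <- tempdir()
  sc <- generate_single_cell_dataset(small_spec(seed = 3, n_genes = 40,
                                                n_cells_per_type = 5))
  for (fmt in c("tsv", "mtx")) {
    prefix <- file.path(dir, paste0("sc_", fmt))
    write_single_cell(sc, prefix, format = fmt)
    back <- read_single_cell(prefix, format = fmt)
    expect_equal(unname(back$counts), unname(sc$counts))
    expect_equal(back$cell_types, sc$cell_types)
  }

  P <- sample_proportions(dirichlet_spec(c(1, 2), 6, seed = 5,
                                         type_names = c("x", "y")))
  ppath <- file.path(dir, "props.tsv")
  write_proportions(P, ppath, comment = "seed=5")
  expect_equal(read_proportions(ppath)$values, P$values, tolerance = 1e-12)

  bulk <- pseudo_bulk(matrix(c(5, 10, 2, 4), 2, 2,
                             dimnames = list(c("g1", "g2"), NULL)),
                      proportion_matrix(matrix(0.5, 2, 2), c("x", "y")))
  write_pseudobulk(bulk, file.path(dir, "pb"))
  back <- read_pseudobulk(file.path(dir, "pb"))
  expect_equal(unname(back$expression), unname(bulk$expression))

  sig <- signature_matrix(make_separable_C(M = 30, K = 2, n_markers = 4))
  spath <- file.path(dir, "sig.tsv")
  write_signature(sig, spath)
  expect_equal(read_signature(spath)$values, sig$values, tolerance = 1e-9)
})

test_that("deconv_fit methods expose the fit", {
  C <- make_separable_C(M = 80, K = 3, n_markers = 6)
  bulk <- make_noiseless_bulk(C, n = 10, seed = 2)
  fit <- deconvolute(bulk, "nnls", signature = signature_matrix(C),
                     truth = bulk$truth)
  expect_equal(dim(coef(fit)), c(3, 10))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.deconv_fit")
  expect_equal(s$metrics$pearson_r, 1, tolerance = 1e-9)
  expect_output(print(fit), "deconv_fit \\(nnls\\)")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
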