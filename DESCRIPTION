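Package: deconvbench
Title: Robustness and Resilience Benchmarking of Bulk RNA-Seq Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation-based benchmarking of cell-type deconvolution for bulk
    RNA sequencing. Generates cell-level expression data with planted marker
    structure, simulates tissue compositions from a Dirichlet model with
    controllable variance, builds pseudo-bulk samples by ideal mixing of
    sampled single cells, applies controlled discrepancies between the
    bulk-generating and reference profiles (mean shifting, cell truncation,
    scaling, variance reduction, platform shift), deconvolves the mixtures
    with desk-scale implementations of four method families (non-negative
    least squares, variance-weighted NNLS, nu-support-vector regression on a
    signature matrix, simplex-corner unmixing and marker/graph-regularized
    non-negative matrix factorization), and scores estimates against ground
    truth with Pearson correlation, root-mean-square deviation and mean
    absolute deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    Matrix,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
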