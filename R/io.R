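# Plain-text readers and writers for the pipeline's artifacts: genes x cells
# matrices as TSV or MatrixMarket with sidecar TSVs, proportion matrices,
# signatures and metric reports as tidy TSV. Writers accept an optional
# provenance comment ('# key=value' header line) which readers skip.

write_tsv_matrix <- function(m, path, id_col, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a cell-level dataset to disk
#'
#' `format = "tsv"` writes `<prefix>_counts.tsv` (gene rows, cell columns)
#' plus `<prefix>_cells.tsv` (cell id, cell type); `format = "mtx"` writes a
#' MatrixMarket `<prefix>_counts.mtx` with sidecars `<prefix>_genes.tsv` and
#' `<prefix>_cells.tsv`.
#'
#' @param data a `single_cell_dataset`.
#' @param prefix path prefix for the output files.
#' @param format `"tsv"` or `"mtx"`.
#' @param comment optional provenance string written as a `#` header (TSV
#'   only).
#' @return invisibly, the paths written.
#' @export
write_single_cell <- function(data, prefix, format = c("tsv", "mtx"),
                              comment = NULL) {
  stopifnot(inherits(data, "single_cell_dataset"))
  format <- match.arg(format)
  cell_ids <- sprintf("cell_%05d", seq_along(data$cell_types))
  cells <- data.frame(cell_id = cell_ids, cell_type = data$cell_types)
  cells_path <- paste0(prefix, "_cells.tsv")
  utils::write.table(cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (format == "tsv") {
    m <- data$counts
    colnames(m) <- cell_ids
    counts_path <- paste0(prefix, "_counts.tsv")
    write_tsv_matrix(m, counts_path, "gene_id", comment)
    paths <- c(counts_path, cells_path)
  } else {
    counts_path <- paste0(prefix, "_counts.mtx")
    genes_path <- paste0(prefix, "_genes.tsv")
    Matrix::writeMM(Matrix::Matrix(data$counts, sparse = TRUE), counts_path)
    utils::write.table(data.frame(gene_id = data$gene_ids), genes_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(counts_path, genes_path, cells_path)
  }
  invisible(paths)
}

#' Read a cell-level dataset written by [write_single_cell()]
#'
#' @param prefix path prefix used when writing.
#' @param format `"tsv"` or `"mtx"`.
#' @return a `single_cell_dataset`.
#' @export
read_single_cell <- function(prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  cells <- utils::read.delim(paste0(prefix, "_cells.tsv"))
  if (format == "tsv") {
    m <- read_tsv_matrix(paste0(prefix, "_counts.tsv"))
    gene_ids <- rownames(m)
  } else {
    m <- as.matrix(Matrix::readMM(paste0(prefix, "_counts.mtx")))
    gene_ids <- utils::read.delim(paste0(prefix, "_genes.tsv"))$gene_id
    rownames(m) <- gene_ids
  }
  new_single_cell_dataset(m, gene_ids, cells$cell_type,
                          unique(cells$cell_type))
}

#' Write a proportion matrix as TSV (types x samples)
#'
#' @param P a [proportion_matrix()].
#' @param path output file.
#' @param comment optional provenance header.
#' @export
write_proportions <- function(P, path, comment = NULL) {
  stopifnot(inherits(P, "proportion_matrix"))
  write_tsv_matrix(P$values, path, "cell_type", comment)
  invisible(path)
}

#' Read a proportion matrix written by [write_proportions()]
#'
#' @param path input file.
#' @return a [proportion_matrix()].
#' @export
read_proportions <- function(path) {
  m <- read_tsv_matrix(path)
  proportion_matrix(m, rownames(m))
}

#' Write a pseudo-bulk dataset (expression + truth) to disk
#'
#' Writes `<prefix>_expression.tsv` and `<prefix>_truth.tsv`.
#'
#' @param bulk a `pseudo_bulk`.
#' @param prefix path prefix.
#' @param comment optional provenance header.
#' @export
write_pseudobulk <- function(bulk, prefix, comment = NULL) {
  stopifnot(inherits(bulk, "pseudo_bulk"))
  write_tsv_matrix(bulk$expression, paste0(prefix, "_expression.tsv"),
                   "gene_id", comment)
  write_proportions(bulk$truth, paste0(prefix, "_truth.tsv"), comment)
  invisible(prefix)
}

#' Read a pseudo-bulk dataset written by [write_pseudobulk()]
#'
#' @param prefix path prefix.
#' @return a `pseudo_bulk`.
#' @export
read_pseudobulk <- function(prefix) {
  m <- read_tsv_matrix(paste0(prefix, "_expression.tsv"))
  truth <- read_proportions(paste0(prefix, "_truth.tsv"))
  pseudo_bulk(m, truth)
}

#' Write a signature matrix as TSV
#'
#' @param sig a [signature_matrix()].
#' @param path output file.
#' @param comment optional provenance header.
#' @export
write_signature <- function(sig, path, comment = NULL) {
  stopifnot(inherits(sig, "signature_matrix"))
  write_tsv_matrix(sig$values, path, "gene_id", comment)
  invisible(path)
}

#' Read a signature matrix written by [write_signature()]
#'
#' @param path input file.
#' @return a [signature_matrix()].
#' @export
read_signature <- function(path) {
  m <- read_tsv_matrix(path)
  signature_matrix(m)
}

#' Write a metric report as tidy TSV
#'
#' @param report a metric-report data.frame (one row per scenario, method,
#'   tier, perturbation).
#' @param path output file.
#' @param comment optional provenance header.
#' @export
write_metric_report <- function(report, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metric report written by [write_metric_report()]
#'
#' @param path input file.
#' @return a data.frame.
#' @export
read_metric_report <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}
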