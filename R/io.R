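# File input/output and preprocessing filters: dense CSV/TSV and sparse
# Matrix Market counts, per-cell batch labels, low-expression and real-data
# filters, and highly-variable-gene pre-screening.

#' Preprocessing configuration
#'
#' @param hvg_count Number of highly variable genes to retain.
#' @param min_reads,min_cells Low-expression gene filter: a gene is kept if at
#'   least `min_cells` cells have at least `min_reads` reads.
#' @param min_genes_per_cell,min_cells_per_gene,min_celltype_frac Real-data
#'   filters: remove cells expressing fewer than `min_genes_per_cell` genes,
#'   genes expressed in fewer than `min_cells_per_gene` cells, and annotated
#'   cell types below `min_celltype_frac` of the population.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hvg_count = 1000L, min_reads = 10L, min_cells = 20L,
                              min_genes_per_cell = 250L, min_cells_per_gene = 50L,
                              min_celltype_frac = 0.03) {
  vals <- c(hvg_count, min_reads, min_cells, min_genes_per_cell,
            min_cells_per_gene, min_celltype_frac)
  if (any(vals < 0)) stop("thresholds must be non-negative", call. = FALSE)
  structure(list(hvg_count = as.integer(hvg_count), min_reads = min_reads,
                 min_cells = min_cells, min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 min_celltype_frac = min_celltype_frac),
            class = "preprocess_config")
}

#' Read a count matrix
#'
#' Dense CSV/TSV (first column = cell ids, header = gene ids) or Matrix Market
#' sparse triplet with companion one-column gene and cell name files.
#' Orientation is normalized to cells x genes; set `transpose = TRUE` when the
#' file stores genes x cells.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, or `.mtx`).
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param genes,cells Companion name files (required for `mtx`).
#' @param transpose Transpose after reading.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        genes = NULL, cells = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop(sprintf("cannot infer format from extension '%s'", ext),
                          call. = FALSE))
  }
  if (format == "mtx") {
    if (is.null(genes) || is.null(cells)) {
      stop("Matrix Market input needs companion 'genes' and 'cells' name files",
           call. = FALSE)
    }
    M <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes)
    cell_ids <- readLines(cells)
    if (transpose) M <- t(M)
    if (nrow(M) != length(cell_ids) || ncol(M) != length(gene_ids)) {
      stop("dimension/name mismatch between matrix and companion files", call. = FALSE)
    }
    return(count_matrix(M, cell_ids, gene_ids))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (transpose) M <- t(M)
  count_matrix(M)
}

#' Write a count matrix
#'
#' Either a dense CSV (cells x genes with ids) or a Matrix Market triplet with
#' `genes.tsv` / `cells.tsv` companions in the same directory.
#'
#' @param X Count matrix.
#' @param path Output path (`.csv` or `.mtx`).
#' @export
write_counts <- function(X, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
    writeLines(colnames(X), file.path(dirname(path), "genes.tsv"))
    writeLines(rownames(X), file.path(dirname(path), "cells.tsv"))
  } else {
    utils::write.csv(as.data.frame(X), path)
  }
  invisible(path)
}

#' Read per-cell batch labels
#'
#' Accepts a plain one-label-per-line file, or a CSV with columns `cell_id`
#' and `batch` (any header containing those names); in the latter case rows
#' are realigned to `cell_ids` when given.
#'
#' @param path File path.
#' @param cell_ids Optional cell identifiers to align against.
#' @return A one-hot [batch_design()] with batches ordered by first appearance.
#' @export
read_batches <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, header = TRUE)
    if (!all(c("cell_id", "batch") %in% names(df))) {
      stop("CSV batch file needs 'cell_id' and 'batch' columns", call. = FALSE)
    }
    labs <- df$batch
    if (!is.null(cell_ids)) {
      idx <- match(cell_ids, df$cell_id)
      if (anyNA(idx)) stop("batch file is missing some cell ids", call. = FALSE)
      labs <- df$batch[idx]
    }
  } else {
    labs <- readLines(path)
    labs <- labs[nzchar(labs)]
    if (!is.null(cell_ids) && length(labs) != length(cell_ids)) {
      stop("batch label count does not match number of cells", call. = FALSE)
    }
  }
  batch_design(labs)
}

#' Low-expression gene filter
#'
#' Excludes genes with low expression: under the default reading a gene is
#' removed when fewer than `min_cells` cells carry at least `min_reads` reads
#' (strict `<`, so a gene with `min_reads` reads in exactly `min_cells` cells
#' is kept). `rule = "total_or_cells"` instead removes genes whose total count
#' is below `min_reads` or that are expressed in fewer than `min_cells` cells.
#'
#' @param X Count matrix.
#' @param cfg A [preprocess_config()].
#' @param rule Filter reading, see above.
#' @return The filtered count matrix (gene order preserved).
#' @export
filter_genes_lowexpr <- function(X, cfg = preprocess_config(),
                                 rule = c("cells_at_threshold", "total_or_cells")) {
  rule <- match.arg(rule)
  keep <- if (rule == "cells_at_threshold") {
    colSums(X >= cfg$min_reads) >= cfg$min_cells
  } else {
    colSums(X) >= cfg$min_reads & colSums(X > 0) >= cfg$min_cells
  }
  X[, keep, drop = FALSE]
}

#' Real-data quality filters
#'
#' Applies, in order: remove cells expressing fewer than `min_genes_per_cell`
#' genes; remove genes expressed in fewer than `min_cells_per_gene` cells;
#' when annotations are given, remove cell types below `min_celltype_frac` of
#' the remaining population. All comparisons are strict (`<`).
#'
#' @param X Count matrix.
#' @param annotations Optional per-cell type labels (cell-type filter skipped
#'   without them).
#' @param cfg A [preprocess_config()].
#' @return The filtered count matrix; kept annotations in attribute
#'   `"annotations"` when provided.
#' @export
filter_real_data <- function(X, annotations = NULL, cfg = preprocess_config()) {
  if (!is.null(annotations)) stopifnot(length(annotations) == nrow(X))
  keep_cells <- rowSums(X > 0) >= cfg$min_genes_per_cell
  X <- X[keep_cells, , drop = FALSE]
  if (!is.null(annotations)) annotations <- annotations[keep_cells]
  keep_genes <- colSums(X > 0) >= cfg$min_cells_per_gene
  X <- X[, keep_genes, drop = FALSE]
  if (!is.null(annotations)) {
    frac <- table(annotations) / nrow(X)
    keep_types <- names(frac)[frac >= cfg$min_celltype_frac]
    keep <- annotations %in% keep_types
    X <- X[keep, , drop = FALSE]
    attr(X, "annotations") <- annotations[keep]
  }
  X
}

#' Highly-variable-gene pre-screening
#'
#' Retains the `hvg_count` genes with the largest per-gene standard deviation
#' of raw counts (ties broken by original gene order); passes through with a
#' warning when fewer genes are available.
#'
#' @param X Count matrix.
#' @param cfg A [preprocess_config()].
#' @param on `"raw"` (default) or `"log"` (log1p-transformed) counts for the
#'   standard deviation.
#' @return Count matrix restricted to the selected genes, original order.
#' @export
hvg_screen <- function(X, cfg = preprocess_config(), on = c("raw", "log")) {
  on <- match.arg(on)
  if (ncol(X) < cfg$hvg_count) {
    warning("fewer genes than hvg_count; returning input unchanged", call. = FALSE)
    return(X)
  }
  if (ncol(X) == cfg$hvg_count) return(X)
  M <- if (on == "log") log1p(X) else X
  sds <- apply(M, 2L, stats::sd)
  ord <- order(-sds, seq_along(sds))
  keep <- sort(ord[seq_len(cfg$hvg_count)])
  X[, keep, drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Counts as Matrix Market plus `genes.tsv` / `cells.tsv`, truth tables
#' (labels, informative flags, dropout mask) as CSV, and the generating
#' parameters as JSON.
#'
#' @param sim A `zinbmix_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$X, file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(cell_id = rownames(sim$X),
                              batch = .batch_index(sim$B),
                              label = sim$labels),
                   file.path(dir, "cells_truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene_id = colnames(sim$X),
                              informative = sim$informative),
                   file.path(dir, "genes_truth.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$dropout_indicators),
                   file.path(dir, "dropout_mask.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(sim$gen_params, function(x) if (is.matrix(x)) unclass(as.data.frame(x)) else x),
    file.path(dir, "gen_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
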