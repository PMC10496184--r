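#' Construct a validated cells-by-genes count matrix
#'
#' Light wrapper that validates a raw scRNA-seq count matrix: entries must be
#' finite non-negative integers, rows are cells, columns are genes. Row and
#' column names are created when absent so downstream results can always refer
#' to cell and gene identifiers.
#'
#' @param values Numeric matrix of counts, cells in rows, genes in columns.
#' @param cell_ids,gene_ids Optional character vectors of identifiers; default
#'   to existing dimnames or `cell1..n` / `gene1..J`.
#' @return An integer-valued matrix with dimnames set, of class `matrix`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("count matrix must be numeric", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("count matrix must have at least one cell and one gene", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("count matrix contains non-finite entries", call. = FALSE)
  if (any(values < 0)) stop("count matrix contains negative entries", call. = FALSE)
  if (any(abs(values - round(values)) > 1e-8)) {
    bad <- which(abs(values - round(values)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at cell %d, gene %d", bad[1L], bad[2L]), call. = FALSE)
  }
  storage.mode(values) <- "double"
  values <- round(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  stopifnot(length(cell_ids) == nrow(values), length(gene_ids) == ncol(values))
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

#' One-hot batch design from per-cell batch labels
#'
#' Batches are ordered by first appearance; every cell belongs to exactly one
#' batch and every batch must contain at least one cell.
#'
#' @param labels Vector of per-cell batch labels (factor, character or integer).
#' @return An `n x S` binary indicator matrix with batch labels as column names.
#' @export
batch_design <- function(labels) {
  if (length(labels) < 1L) stop("empty batch label vector", call. = FALSE)
  lev <- unique(as.character(labels))
  f <- factor(as.character(labels), levels = lev)
  B <- matrix(0, length(labels), length(lev), dimnames = list(NULL, lev))
  B[cbind(seq_along(labels), as.integer(f))] <- 1
  B
}

.validate_batch <- function(B, n = NULL) {
  if (!is.matrix(B)) stop("batch design must be a matrix", call. = FALSE)
  if (!is.null(n) && nrow(B) != n) stop("batch design rows must match number of cells", call. = FALSE)
  if (any(B != 0 & B != 1)) stop("batch design must be binary", call. = FALSE)
  if (any(rowSums(B) != 1)) stop("each cell must belong to exactly one batch", call. = FALSE)
  if (any(colSums(B) == 0)) stop("every batch must contain at least one cell", call. = FALSE)
  invisible(B)
}

.batch_index <- function(B) max.col(B, ties.method = "first")

#' Parameter set of the zero-inflated negative binomial mixture
#'
#' Bundles the full parameter vector of the model: mixing proportions `p`,
#' cluster-specific dropout probabilities `pi` (J x K), cluster-specific
#' log-scale means `beta` (J x K), per-gene dispersions `phi`, batch
#' coefficients `gamma` (length S, reference batch fixed at 0), and the
#' pre-estimated global log-means `beta_star` toward which `beta` is shrunk.
#'
#' @param p Numeric vector of K mixing proportions (non-negative, sums to 1).
#' @param pi J x K matrix of dropout probabilities in \[0, 1\].
#' @param beta J x K matrix of log-scale cluster means.
#' @param phi Positive numeric vector of J gene-wise dispersions.
#' @param gamma Numeric vector of S batch coefficients.
#' @param beta_star Numeric vector of J global log-means.
#' @return An object of class `zinbmix_params`.
#' @export
zinbmix_params <- function(p, pi, beta, phi, gamma, beta_star) {
  p <- as.numeric(p); phi <- as.numeric(phi)
  gamma <- as.numeric(gamma); beta_star <- as.numeric(beta_star)
  pi <- as.matrix(pi); beta <- as.matrix(beta)
  K <- length(p); J <- length(phi); S <- length(gamma)
  if (any(p < -1e-12)) stop("mixing proportions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12) stop("mixing proportions must sum to 1", call. = FALSE)
  if (!all(dim(pi) == c(J, K)) || !all(dim(beta) == c(J, K))) {
    stop("pi and beta must be J x K matrices", call. = FALSE)
  }
  if (any(pi < 0 | pi > 1)) stop("dropout probabilities must lie in [0, 1]", call. = FALSE)
  if (any(phi <= 0) || any(!is.finite(phi))) stop("dispersions must be positive and finite", call. = FALSE)
  if (length(beta_star) != J) stop("beta_star must have one entry per gene", call. = FALSE)
  structure(
    list(p = p, pi = pi, beta = beta, phi = phi, gamma = gamma,
         beta_star = beta_star, K = K, J = J, S = S),
    class = "zinbmix_params"
  )
}

#' @export
print.zinbmix_params <- function(x, ...) {
  cat(sprintf("ZINB mixture parameters: K = %d clusters, J = %d genes, S = %d batches\n",
              x$K, x$J, x$S))
  cat("mixing proportions:", paste(signif(x$p, 4), collapse = " "), "\n")
  invisible(x)
}
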