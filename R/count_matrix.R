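#' Sparse gene-by-cell count matrix
#'
#' Light S3 container around a `Matrix::dgCMatrix` holding raw, non-negative
#' integer transcript counts with genes as rows and cells as columns. All
#' transformations in this package start from this object; counts are kept
#' sparse throughout and per-cell offsets are never materialised into the
#' matrix.
#'
#' @param values matrix-like object of non-negative integer counts
#'   (genes x cells); coerced to `dgCMatrix`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#'   Defaults to existing rownames.
#' @param cell_ids character vector of unique cell identifiers (columns).
#'   Defaults to existing colnames.
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  if (!inherits(values, "Matrix"))
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  x <- values@x
  if (length(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    if (any(abs(x - round(x)) > 1e-8))
      stop("counts must be integral; got non-integer values")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  nnz <- length(x$values@x)
  cat("count_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (", format(100 * (1 - nnz / prod(dim(x$values))), digits = 3),
      "% zero)\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Per-cell total counts
#'
#' @param X a `count_matrix`.
#' @return Named numeric vector of column sums S_j.
#' @export
cell_totals <- function(X) {
  stopifnot(inherits(X, "count_matrix"))
  s <- Matrix::colSums(X$values)
  names(s) <- X$cell_ids
  s
}

#' Per-cell number of detected genes
#'
#' @param X a `count_matrix`.
#' @return Named integer vector of non-zero entries per column.
#' @export
cells_detected_genes <- function(X) {
  d <- Matrix::colSums(X$values > 0)
  names(d) <- X$cell_ids
  d
}

# internal: subset keeping class invariants
subset_counts <- function(X, genes = NULL, cells = NULL) {
  v <- X$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  count_matrix(v, rownames(v), colnames(v))
}
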