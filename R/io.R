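open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

find_10x_file <- function(dir, stem) {
  for (cand in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz"))))
    if (file.exists(cand)) return(cand)
  NULL
}

#' Read a count matrix from 10x MatrixMarket triplet or CSV
#'
#' A directory is interpreted as a 10x-style bundle: `matrix.mtx[.gz]`
#' (genes as rows), `features.tsv[.gz]` or `genes.tsv[.gz]` (first column
#' used as gene id), `barcodes.tsv[.gz]`. A file is read as dense CSV with
#' gene ids in the first column and cell ids in the header; pass
#' `transpose = TRUE` for cells x genes CSVs. Duplicate gene ids are
#' suffixed deterministically (`make.unique`). Non-integer values are
#' rejected with a clear error.
#'
#' @param path directory (MatrixMarket bundle) or CSV file, gzip supported.
#' @param transpose logical; CSV is cells x genes.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, transpose = FALSE) {
  if (dir.exists(path)) {
    mtx <- find_10x_file(path, "matrix.mtx")
    if (is.null(mtx)) stop("no matrix.mtx[.gz] in ", path)
    m <- Matrix::readMM(mtx)
    feat <- find_10x_file(path, "features.tsv")
    if (is.null(feat)) feat <- find_10x_file(path, "genes.tsv")
    bc <- find_10x_file(path, "barcodes.tsv")
    if (is.null(feat) || is.null(bc))
      stop("features/genes and barcodes tables required in ", path)
    genes <- utils::read.delim(open_maybe_gz(feat), header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.delim(open_maybe_gz(bc), header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    if (length(genes) != nrow(m))
      stop("features table has ", length(genes), " rows but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("barcodes table has ", length(cells), " rows but matrix has ",
           ncol(m), " columns")
    count_matrix(m, make.unique(genes), make.unique(cells))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(open_maybe_gz(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
    ids <- make.unique(as.character(df[[1L]]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in ", path)
    rownames(m) <- ids
    if (transpose) m <- t(m)
    count_matrix(m, rownames(m), colnames(m))
  }
}

#' Write a count matrix as a 10x-style MatrixMarket bundle
#'
#' @param X a [count_matrix()].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(X, dir) {
  stopifnot(inherits(X, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- X$values
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(X$gene_ids), file.path(dir, "features.tsv"),
                     sep = "\t", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(X$cell_ids), file.path(dir, "barcodes.tsv"),
                     sep = "\t", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' Write a transformed matrix as CSV (components x cells)
#'
#' @param M a `logratio_matrix`, `lognorm_matrix`, or matrix.
#' @param path output CSV path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_transformed <- function(M, path) {
  V <- as_lr_values(M)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else path
  utils::write.csv(as.data.frame(V), con, row.names = TRUE)
  invisible(path)
}
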