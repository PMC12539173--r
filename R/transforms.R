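#' @name logratio_matrix
#' @title Dense log-ratio representation of a count matrix
#'
#' @description Result container for the log-ratio transformations. `values`
#' is a dense numeric matrix with output components as rows (genes for the
#' centered and housekeeping-gene log-ratios, D-1 pivot coordinates for the
#' isometric log-ratio) and cells as columns. `transform` and `scheme`
#' record provenance.
#' @keywords internal
NULL

new_logratio_matrix <- function(values, transform, scheme = NULL,
                                component_ids = rownames(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)))
    stop("log-ratio values must be finite; check offsets/input")
  rownames(values) <- component_ids
  structure(list(values = values, transform = transform, scheme = scheme,
                 component_ids = component_ids),
            class = "logratio_matrix")
}

#' @export
print.logratio_matrix <- function(x, ...) {
  cat("logratio_matrix [", x$transform, "]: ", nrow(x$values),
      " components x ", ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.logratio_matrix <- function(x) dim(x$values)

# internal: per-nonzero column index of a dgCMatrix
col_index <- function(v) rep.int(seq_len(ncol(v)), diff(v@p))

# internal: log(x_ij + delta_j) for every gene/cell without densifying:
# returns list(lx = log value per stored nonzero, lz = log value of a zero
# entry per cell, colsum = per-cell sum of logs over ALL D genes, nnz = per
# cell nonzero count). HALFMIN adds delta to zero entries only.
log_shifted <- function(X, delta, halfmin = FALSE) {
  v <- X$values
  j <- col_index(v)
  lx <- if (halfmin) log(v@x) else log(v@x + delta[j])
  lz <- log(delta)
  nnz <- diff(v@p)
  nzsum <- numeric(ncol(v))
  if (length(lx)) {
    sums <- rowsum(lx, group = j)
    nzsum[as.integer(rownames(sums))] <- sums[, 1L]
  }
  list(lx = lx, lz = lz, nnz = nnz,
       colsum = nzsum + (nrow(v) - nnz) * lz)
}

# internal: dense matrix of log(x + delta) for a subset of genes, O(nnz + N*g)
dense_log_rows <- function(X, delta, genes, halfmin = FALSE) {
  v <- X$values[genes, , drop = FALSE]
  out <- matrix(rep(log(delta), each = length(genes)),
                nrow = length(genes), ncol = ncol(v),
                dimnames = list(genes, X$cell_ids))
  if (length(v@x)) {
    j <- col_index(v)
    i <- v@i + 1L
    out[cbind(i, j)] <- if (halfmin) log(v@x) else log(v@x + delta[j])
  }
  out
}

resolve_genes <- function(X, genes_out) {
  if (is.null(genes_out)) return(X$gene_ids)
  genes_out <- as.character(genes_out)
  bad <- setdiff(genes_out, X$gene_ids)
  if (length(bad))
    stop("unknown genes: ", paste(utils::head(bad, 5L), collapse = ", "))
  genes_out
}

#' Centered log-ratio transformation of raw counts
#'
#' Adds the scheme's per-cell offset to every count, closes each cell to a
#' composition, and takes the log of each part over the geometric mean of all
#' parts of that cell. Computed entirely in log space and sparsity-aware:
#' the zeros of a cell share the single value `log(delta_j)`, so the per-cell
#' geometric mean costs O(nnz + N) and no dense D x N intermediate is built
#' when `genes_out` restricts the output.
#'
#' The geometric-mean denominator always runs over all D genes, even when
#' `genes_out` selects a subset of output rows. (Some ecosystems center on
#' the subset instead; here the denominator is fixed to the full gene set so
#' that the transformation agrees with the log-normalization bridge, see
#' [clr_from_lognorm()].)
#'
#' @param X a [count_matrix()].
#' @param scheme an [addition_scheme()]; default SGM.
#' @param genes_out optional character vector of genes to return rows for.
#' @return A `logratio_matrix` (genes x cells) whose columns sum to zero
#'   when `genes_out` is the full gene set.
#' @export
clr <- function(X, scheme = addition_scheme("SGM"), genes_out = NULL) {
  stopifnot(inherits(X, "count_matrix"))
  if (nrow(X$values) == 0L || ncol(X$values) == 0L) stop("empty matrix")
  genes <- resolve_genes(X, genes_out)
  delta <- compute_cell_offsets(X, scheme)
  halfmin <- scheme$kind == "HALFMIN"
  ls <- log_shifted(X, delta, halfmin)
  gmean <- ls$colsum / nrow(X$values)
  out <- dense_log_rows(X, delta, genes, halfmin)
  out <- sweep(out, 2L, gmean, "-")
  new_logratio_matrix(out, "CLR", scheme, genes)
}

#' Isometric log-ratio (pivot coordinates) of raw counts
#'
#' Orthonormal pivot (sequential binary partition) coordinates: component i
#' contrasts part i against the geometric mean of parts i+1..D, scaled by
#' sqrt((D-i)/(D-i+1)). The D-part simplex maps to D-1 Euclidean
#' coordinates preserving Aitchison distances, so per-cell norms equal the
#' centered log-ratio norms. Gene order is the input order; permuting genes
#' changes individual coordinates but no distances.
#'
#' Implemented with per-column suffix sums of the log-shifted counts, so the
#' per-cell cost is O(D) rather than O(D^2).
#'
#' @inheritParams clr
#' @return A `logratio_matrix` with D-1 rows named `ilr1..ilr(D-1)`.
#' @export
ilr <- function(X, scheme = addition_scheme("SGM")) {
  stopifnot(inherits(X, "count_matrix"))
  D <- nrow(X$values)
  if (D < 2L) stop("isometric log-ratio requires at least 2 genes")
  delta <- compute_cell_offsets(X, scheme)
  halfmin <- scheme$kind == "HALFMIN"
  L <- dense_log_rows(X, delta, X$gene_ids, halfmin)
  # suffix[i, j] = sum_{k >= i} L[k, j]
  suffix <- matrix(apply(L, 2L, function(col) rev(cumsum(rev(col)))),
                   nrow = D)
  i <- seq_len(D - 1L)
  coef <- sqrt((D - i) / (D - i + 1))
  out <- coef * (L[i, , drop = FALSE] -
                   suffix[i + 1L, , drop = FALSE] / (D - i))
  new_logratio_matrix(out, "ILR", scheme,
                      component_ids = paste0("ilr", i))
}

#' Housekeeping-gene log-ratio of raw counts
#'
#' Log-ratio of every gene against the geometric mean of a housekeeping-gene
#' panel (default SDHA, ACTB, UBC, YWHAZ, GAPDH), a knowledge-based
#' alternative to the all-gene denominator of [clr()].
#'
#' @inheritParams clr
#' @param hkg character vector of reference gene identifiers; all must be
#'   present in `X`.
#' @return A `logratio_matrix` (genes x cells).
#' @export
hkglr <- function(X, scheme = addition_scheme("SGM"),
                  hkg = c("SDHA", "ACTB", "UBC", "YWHAZ", "GAPDH")) {
  stopifnot(inherits(X, "count_matrix"))
  if (length(hkg) == 0L) stop("housekeeping gene list must be non-empty")
  hkg <- as.character(hkg)
  missing <- setdiff(hkg, X$gene_ids)
  if (length(missing))
    stop("housekeeping genes absent from matrix: ",
         paste(missing, collapse = ", "))
  delta <- compute_cell_offsets(X, scheme)
  halfmin <- scheme$kind == "HALFMIN"
  L <- dense_log_rows(X, delta, X$gene_ids, halfmin)
  denom <- colMeans(L[hkg, , drop = FALSE])
  out <- sweep(L, 2L, denom, "-")
  new_logratio_matrix(out, "HKGLR", scheme, X$gene_ids)
}

#' Conventional log-normalization
#'
#' Scales each cell to `scale_factor` total counts and applies log1p
#' (natural log): `log(x_ij * scale_factor / S_j + 1)`. Zeros stay zero, so
#' the result remains sparse.
#'
#' @param X a [count_matrix()].
#' @param scale_factor positive scaling constant, conventionally 10,000.
#' @return A `lognorm_matrix` with sparse `values` and the recorded
#'   `scale_factor`.
#' @export
lognormalize <- function(X, scale_factor = 10000) {
  stopifnot(inherits(X, "count_matrix"))
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be positive")
  s <- cell_totals(X)
  if (any(s == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(names(s)[s == 0], 5L), collapse = ", "))
  v <- X$values
  if (length(v@x)) {
    j <- col_index(v)
    v@x <- log1p(v@x * scale_factor / s[j])
  }
  structure(list(values = v, scale_factor = scale_factor,
                 gene_ids = X$gene_ids, cell_ids = X$cell_ids),
            class = "lognorm_matrix")
}

#' @export
print.lognorm_matrix <- function(x, ...) {
  cat("lognorm_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (scale_factor = ", x$scale_factor, ")\n", sep = "")
  invisible(x)
}

#' Centered log-ratio from an already log-normalized matrix
#'
#' Log-normalized values are, up to a per-cell additive constant, the logs of
#' counts offset by S_j / scale_factor. Centering each cell by the mean over
#' the chosen gene set therefore recovers the centered log-ratio exactly:
#' with `genes_center = NULL` (all genes) the output equals
#' `clr(X, addition_scheme("S10000"))` elementwise when the scale factor is
#' 10,000. This makes public datasets distributed only in log-normalized
#' form usable for compositional analysis without access to raw counts.
#'
#' @param LN a `lognorm_matrix` from [lognormalize()], or any matrix of
#'   log-normalized values (genes x cells).
#' @param genes_center optional gene subset used for the per-cell centering
#'   mean; default all genes.
#' @return A `logratio_matrix` (genes x cells).
#' @export
clr_from_lognorm <- function(LN, genes_center = NULL) {
  if (inherits(LN, "lognorm_matrix")) {
    v <- LN$values
    gene_ids <- LN$gene_ids
  } else {
    v <- LN
    gene_ids <- rownames(v)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(v)))
  }
  if (is.null(genes_center)) {
    genes_center <- gene_ids
  } else {
    genes_center <- as.character(genes_center)
    if (length(genes_center) == 0L) stop("empty centering gene set")
    bad <- setdiff(genes_center, gene_ids)
    if (length(bad))
      stop("unknown centering genes: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  dense <- as.matrix(v)
  rownames(dense) <- gene_ids
  center <- colMeans(dense[genes_center, , drop = FALSE])
  out <- sweep(dense, 2L, center, "-")
  new_logratio_matrix(out, "CLR_FROM_LOGNORM", NULL, gene_ids)
}
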