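#' @name embedding_result
#' @title Principal-component embedding of a log-ratio matrix
#' @description Container returned by [pca_truncated()] and [lra_exact()]:
#' `scores` (cells x k), `loadings` (genes x k), `singular_values`
#' (non-increasing), and `variance_explained` (fraction of total variance of
#' the centered matrix captured by each component).
#' @keywords internal
NULL

new_embedding_result <- function(scores, loadings, d, total_ss, method) {
  k <- length(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 singular_values = d,
                 variance_explained = d^2 / total_ss,
                 method = method),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("embedding_result [", x$method, "]: ", nrow(x$scores), " cells x ",
      length(x$singular_values), " components (",
      format(100 * sum(x$variance_explained), digits = 3),
      "% variance)\n", sep = "")
  invisible(x)
}

# SVD signs are arbitrary per component; fix them so the loading of largest
# absolute value is positive.
fix_svd_signs <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    piv <- which.max(abs(U[, k]))
    if (U[piv, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

center_rows <- function(M) M - rowMeans(M)

as_lr_values <- function(M) {
  if (inherits(M, "logratio_matrix")) M$values
  else if (inherits(M, "lognorm_matrix")) as.matrix(M$values)
  else as.matrix(M)
}

#' Exact log-ratio analysis (full-SVD oracle)
#'
#' Log-ratio analysis is principal component analysis applied to the centered
#' log-ratio representation. This routine removes the per-gene mean (the
#' CLR input is already column-centered, so the result is double-centered)
#' and takes a full singular value decomposition. It is intended for small
#' matrices and serves as the exactness oracle for [pca_truncated()]; the
#' truncated path is the one that scales to real data.
#'
#' @param M a `logratio_matrix` (or plain genes x cells matrix).
#' @param k number of components to return.
#' @return An `embedding_result`.
#' @export
lra_exact <- function(M, k = 10L) {
  V <- as_lr_values(M)
  if (k > min(dim(V))) stop("k exceeds min(genes, cells)")
  C <- center_rows(V)
  sv <- svd(C)
  s <- fix_svd_signs(sv$u[, seq_len(k), drop = FALSE],
                     sv$v[, seq_len(k), drop = FALSE])
  scores <- s$V %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- colnames(V)
  rownames(s$U) <- rownames(V)
  new_embedding_result(scores, s$U, sv$d[seq_len(k)], sum(C^2), "lra_exact")
}

#' Truncated-SVD principal components of a log-ratio matrix
#'
#' Per-gene mean-centering followed by a partial singular value decomposition
#' via implicitly restarted Lanczos bidiagonalization (irlba). On small
#' inputs the component scores agree with the exact [lra_exact()] oracle up
#' to per-component sign; signs are normalized so the largest-magnitude
#' loading of each component is positive. Deterministic for a given seed.
#'
#' @param M a `logratio_matrix` (or plain genes x cells matrix).
#' @param k number of components (default 10, the usual clustering input).
#' @param seed integer seed for the Lanczos starting vector.
#' @return An `embedding_result`.
#' @export
pca_truncated <- function(M, k = 10L, seed = 1L) {
  V <- as_lr_values(M)
  if (any(!is.finite(V))) stop("non-finite values in input")
  if (k >= min(dim(V))) stop("k must be < min(genes, cells)")
  C <- center_rows(V)
  set.seed(seed)
  sv <- irlba::irlba(C, nv = k, nu = k)
  s <- fix_svd_signs(sv$u, sv$v)
  scores <- s$V %*% diag(sv$d, k, k)
  rownames(scores) <- colnames(V)
  rownames(s$U) <- rownames(V)
  new_embedding_result(scores, s$U, sv$d, sum(C^2), "pca_truncated")
}
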