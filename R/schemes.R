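#' Count-addition schemes for sparse compositions
#'
#' Log-ratio transformations require strictly positive parts, so a positive
#' offset (pseudocount) is added to every raw count before closure. Because
#' sequencing depth varies across cells, a single constant is a poor choice
#' for sparse single-cell matrices; cell-specific offsets proportional to the
#' cell total S_j behave much better. Available kinds:
#'
#' \describe{
#'   \item{CONSTANT}{delta_j = `constant` for every cell (classically 1,
#'     0.01, or 0.0001).}
#'   \item{S10000}{delta_j = S_j / 10000 — the offset implicitly used by
#'     conventional log-normalization with scale factor 10,000.}
#'   \item{SMAX}{delta_j = S_j / max_k(S_k); the largest offset is exactly 1.}
#'   \item{SGM}{delta_j = S_j / GM_k(S_k) where GM is the geometric mean of
#'     all cell totals; the geometric mean of the offsets is exactly 1.}
#'   \item{HALFMIN}{half the smallest non-zero count of each cell, added to
#'     zero entries only. Provided for completeness; known to perform poorly
#'     on sparse single-cell data and not recommended.}
#' }
#'
#' @param kind one of `"CONSTANT"`, `"S10000"`, `"SMAX"`, `"SGM"`,
#'   `"HALFMIN"`.
#' @param constant positive value used only for `kind = "CONSTANT"`.
#' @return An object of class `addition_scheme`.
#' @export
addition_scheme <- function(kind = c("CONSTANT", "S10000", "SMAX", "SGM",
                                     "HALFMIN"),
                            constant = 1) {
  kind <- match.arg(kind)
  if (kind == "CONSTANT") {
    if (!is.numeric(constant) || length(constant) != 1L || constant <= 0)
      stop("constant must be a single positive number")
  }
  structure(list(kind = kind, constant = constant), class = "addition_scheme")
}

#' @export
print.addition_scheme <- function(x, ...) {
  cat("addition_scheme:", x$kind,
      if (x$kind == "CONSTANT") paste0("(constant = ", x$constant, ")") else "",
      "\n")
  invisible(x)
}

#' Per-cell offsets delta_j for a count-addition scheme
#'
#' @param X a `count_matrix`; every cell total S_j must be positive.
#' @param scheme an `addition_scheme`.
#' @return Numeric vector of strictly positive offsets, one per cell. For
#'   `HALFMIN` the offset applies to zero entries only (see
#'   [addition_scheme()]).
#' @export
compute_cell_offsets <- function(X, scheme) {
  stopifnot(inherits(X, "count_matrix"), inherits(scheme, "addition_scheme"))
  s <- cell_totals(X)
  if (any(s == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(names(s)[s == 0], 5L), collapse = ", "))
  delta <- switch(scheme$kind,
    CONSTANT = rep(scheme$constant, length(s)),
    S10000   = s / 10000,
    SMAX     = s / max(s),
    # geometric mean via mean of logs: products overflow at realistic N
    SGM      = s / exp(mean(log(s))),
    HALFMIN  = {
      v <- X$values
      minnz <- vapply(seq_along(s), function(j) {
        xs <- v@x[(v@p[j] + 1L):v@p[j + 1L]]
        min(xs)
      }, numeric(1))
      minnz / 2
    })
  names(delta) <- X$cell_ids
  delta
}
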