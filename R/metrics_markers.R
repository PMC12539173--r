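#' Rank-based AUROC of one gene for one cell-type contrast
#'
#' Area under the receiver operating characteristic curve computed from
#' ranks (Mann-Whitney statistic with midrank tie handling):
#' `AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)` where `R_pos` is
#' the rank sum of the positive class. Distribution-free, so applicable
#' unchanged to counts, log-normalized values, or any log-ratio
#' representation.
#'
#' @param values numeric expression value per cell.
#' @param positive logical per cell; `TRUE` marks the positive class.
#' @return Scalar in [0, 1]; 0.5 means no separation.
#' @export
marker_auc <- function(values, positive) {
  positive <- as.logical(positive)
  if (length(values) != length(positive)) stop("length mismatch")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be non-empty")
  r <- rank(values)  # midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUROC table for a panel of marker genes
#'
#' @param M a `logratio_matrix`, `lognorm_matrix`, or genes x cells matrix.
#' @param genes character vector of genes to score.
#' @param positive logical per cell marking the target cell type.
#' @return Named numeric vector of per-gene AUROC values.
#' @export
marker_auc_table <- function(M, genes, positive) {
  V <- as_lr_values(M)
  bad <- setdiff(genes, rownames(V))
  if (length(bad))
    stop("genes absent from matrix: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  vapply(genes, function(g) marker_auc(V[g, ], positive), numeric(1))
}

#' Fraction of markers exceeding AUROC cutoffs
#'
#' For each cutoff, the fraction of candidate marker genes with AUROC
#' strictly above it. When a table of known non-markers is supplied, the
#' same fractions over that null panel estimate the false-positive rate of
#' calling biomarkers at each cutoff.
#'
#' @param auc_table named numeric vector of per-gene AUROC values for
#'   candidate markers.
#' @param cutoffs numeric cutoffs (default 0.6, 0.75, 0.9).
#' @param null_auc_table optional AUROC values for known non-markers.
#' @return List with `fraction_above` (named by cutoff) and, when a null
#'   table is given, `false_positive_fraction`.
#' @export
marker_panel_report <- function(auc_table, cutoffs = c(0.6, 0.75, 0.9),
                                null_auc_table = NULL) {
  if (length(auc_table) == 0L) stop("empty AUROC table")
  frac <- vapply(cutoffs, function(ct) mean(auc_table > ct), numeric(1))
  names(frac) <- paste0("auc_gt_", cutoffs)
  out <- list(fraction_above = frac)
  if (!is.null(null_auc_table) && length(null_auc_table)) {
    fp <- vapply(cutoffs, function(ct) mean(null_auc_table > ct), numeric(1))
    names(fp) <- paste0("auc_gt_", cutoffs)
    out$false_positive_fraction <- fp
  }
  out
}
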