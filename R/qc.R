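#' Quality-control parameters
#'
#' @param min_genes_per_cell remove cells detecting fewer genes than this
#'   (default 200).
#' @param min_cells_per_gene remove genes detected in fewer cells than this
#'   (default 10).
#' @param mt_prefix gene-id prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @param outlier_mads cells whose log1p total counts, log1p detected genes,
#'   or mitochondrial percentage deviate more than this many
#'   median-absolute-deviations from the median are removed (default 3;
#'   `Inf` disables). Counts/features are trimmed on both sides,
#'   mitochondrial percentage on the upper side only.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200L, min_cells_per_gene = 10L,
                      mt_prefix = "MT-", outlier_mads = 3) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0,
            outlier_mads > 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 mt_prefix = mt_prefix, outlier_mads = outlier_mads),
            class = "qc_params")
}

#' Percent mitochondrial counts per cell
#'
#' @param X a [count_matrix()].
#' @param mt_prefix gene-id prefix identifying mitochondrial genes.
#' @return Numeric vector, per-cell mitochondrial counts / total counts x 100.
#' @export
percent_mito <- function(X, mt_prefix = "MT-") {
  mt <- startsWith(X$gene_ids, mt_prefix)
  s <- cell_totals(X)
  if (!any(mt)) return(stats::setNames(rep(0, length(s)), X$cell_ids))
  100 * Matrix::colSums(X$values[mt, , drop = FALSE]) / s
}

mad_outlier <- function(x, nmads, upper_only = FALSE) {
  med <- stats::median(x)
  dev <- stats::mad(x)
  if (dev == 0) return(rep(FALSE, length(x)))
  hi <- x > med + nmads * dev
  if (upper_only) hi else hi | (x < med - nmads * dev)
}

#' Remove low-quality cells
#'
#' Two passes: (1) cells detecting fewer than `min_genes_per_cell` genes are
#' removed; (2) among the survivors, cells whose log1p total counts, log1p
#' detected genes, or mitochondrial percentage are more than `outlier_mads`
#' median-absolute-deviations from the median are removed. The returned
#' report lists every removed cell and the reason.
#'
#' @param X a [count_matrix()].
#' @param p a [qc_params()].
#' @return List with `counts` (filtered `count_matrix`) and `report`
#'   (data.frame: `cell_id`, `reason`).
#' @export
filter_cells <- function(X, p = qc_params()) {
  stopifnot(inherits(X, "count_matrix"), inherits(p, "qc_params"))
  detected <- cells_detected_genes(X)
  low <- detected < p$min_genes_per_cell
  report <- data.frame(cell_id = X$cell_ids[low],
                       reason = rep("min_genes_per_cell", sum(low)),
                       stringsAsFactors = FALSE)
  keep <- X$cell_ids[!low]
  if (length(keep) == 0L) stop("all cells removed by min_genes_per_cell")
  Xk <- subset_counts(X, cells = keep)
  if (is.finite(p$outlier_mads)) {
    out_counts <- mad_outlier(log1p(cell_totals(Xk)), p$outlier_mads)
    out_feats <- mad_outlier(log1p(cells_detected_genes(Xk)), p$outlier_mads)
    out_mt <- mad_outlier(percent_mito(Xk, p$mt_prefix), p$outlier_mads,
                          upper_only = TRUE)
    out <- out_counts | out_feats | out_mt
    if (any(out)) {
      why <- ifelse(out_counts, "outlier_ncount",
                    ifelse(out_feats, "outlier_nfeature", "outlier_pct_mt"))
      report <- rbind(report,
                      data.frame(cell_id = Xk$cell_ids[out],
                                 reason = why[out],
                                 stringsAsFactors = FALSE))
      if (all(out)) stop("all cells removed by outlier filtering")
      Xk <- subset_counts(Xk, cells = Xk$cell_ids[!out])
    }
  }
  list(counts = Xk, report = report)
}

#' Remove rarely detected genes
#'
#' Drops genes with a non-zero count in fewer than `min_cells_per_gene`
#' cells. Applied after [filter_cells()] in the standard pipeline (cells
#' first, then genes).
#'
#' @param X a [count_matrix()].
#' @param p a [qc_params()].
#' @return A filtered `count_matrix`.
#' @export
filter_genes <- function(X, p = qc_params()) {
  stopifnot(inherits(X, "count_matrix"), inherits(p, "qc_params"))
  ncells <- Matrix::rowSums(X$values > 0)
  keep <- ncells >= p$min_cells_per_gene
  if (!any(keep)) stop("all genes removed by min_cells_per_gene")
  subset_counts(X, genes = X$gene_ids[keep])
}

#' Select highly variable genes
#'
#' Returns the `n` genes with the largest per-gene variance of the supplied
#' transformed matrix, so each pipeline selects on its own representation.
#' Ties are broken deterministically by lexicographic gene id.
#'
#' @param M a `logratio_matrix`, `lognorm_matrix`, or plain genes x cells
#'   matrix with rownames.
#' @param n number of genes to select (default 3000, capped at the number
#'   of genes available).
#' @return Character vector of gene ids, ordered by decreasing variance.
#' @export
select_hvg <- function(M, n = 3000L) {
  if (n <= 0) stop("n must be positive")
  V <- as_lr_values(M)
  ids <- rownames(V)
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(V)))
  n <- min(n, nrow(V))
  v <- apply(V, 1L, stats::var)
  ord <- order(-v, ids)
  ids[ord][seq_len(n)]
}
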