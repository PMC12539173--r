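check_partitions <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("partitions label different numbers of cells")
  if (length(pred) == 0L) stop("empty partitions")
  pn <- names(pred); tn <- names(truth)
  if (!is.null(pn) && !is.null(tn)) {
    if (!setequal(pn, tn)) stop("partitions label different cell sets")
    truth <- truth[pn]
  }
  list(pred = as.character(pred), truth = as.character(truth))
}

#' Entropy of accuracy (H_acc)
#'
#' Mean over predicted clusters of the entropy of true-group composition
#' within each cluster:
#' `H_acc = -(sum_i sum_j p_i(x_j) log p_i(x_j)) / M`, natural log, where
#' `p_i(x_j)` is the proportion of cluster i occupied by true group j and M
#' the number of predicted clusters. Bounded by `0 <= H_acc <= log(M)`;
#' smaller is better (each predicted cluster pure in one true group gives 0).
#'
#' @param pred predicted cluster label per cell (vector, any label type).
#' @param truth true group label per cell; if both vectors are named the
#'   names must describe the same cell set.
#' @return Non-negative scalar.
#' @export
entropy_accuracy <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  tab <- table(z$pred, z$truth)
  p <- tab / rowSums(tab)
  plogp <- ifelse(p > 0, p * log(p), 0)
  -sum(plogp) / nrow(tab)
}

#' Entropy of purity (H_pur)
#'
#' The mirror of [entropy_accuracy()]: mean over true groups of the entropy
#' of predicted-cluster composition within each group, divided by the number
#' of true groups N. Bounded by `0 <= H_pur <= log(N)`; smaller is better.
#'
#' @inheritParams entropy_accuracy
#' @return Non-negative scalar.
#' @export
entropy_purity <- function(pred, truth) {
  entropy_accuracy(truth, pred)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' with contingency counts n_ij, row sums a_i, column sums b_j,
#' `ARI = (sum C(n_ij,2) - E) / (max - E)` where
#' `E = sum C(a_i,2) sum C(b_j,2) / C(n,2)` and
#' `max = (sum C(a_i,2) + sum C(b_j,2)) / 2`. Equals 1 for identical
#' partitions and is ~0 for independent ones.
#'
#' @inheritParams entropy_accuracy
#' @return Scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  tab <- table(z$pred, z$truth)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' `NMI = 2 I(G, Ghat) / (H(G) + H(Ghat))` with natural-log entropies and
#' mutual information of the joint label distribution. 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @inheritParams entropy_accuracy
#' @return Scalar in [0, 1].
#' @export
normalized_mutual_information <- function(pred, truth) {
  z <- check_partitions(pred, truth)
  tab <- table(z$pred, z$truth)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  hp <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  ht <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  # both partitions single-cluster: identical as partitions, define as 1
  if (hp + ht == 0) return(1)
  outer_p <- outer(pa, pb)
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer_p), 0))
  2 * mi / (hp + ht)
}

#' Baseline-delta report
#'
#' Reproduces the convention of reporting every method's metric relative to
#' the log-normalization baseline: higher-is-better metrics (ARI, NMI, SCC,
#' POS, AUC) as method minus baseline, entropies (H_acc, H_pur) as baseline
#' minus method, so positive deltas always mean improvement.
#'
#' @param metrics named numeric vector of a method's metrics.
#' @param baseline named numeric vector of the baseline's metrics (same
#'   names).
#' @return Named numeric vector of deltas.
#' @export
baseline_delta <- function(metrics, baseline) {
  stopifnot(setequal(names(metrics), names(baseline)))
  baseline <- baseline[names(metrics)]
  lower_better <- grepl("^(H_acc|H_pur|h_acc|h_pur)", names(metrics))
  out <- ifelse(lower_better, baseline - metrics, metrics - baseline)
  stats::setNames(out, names(metrics))
}
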