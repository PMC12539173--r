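#' Trajectory ground truth
#'
#' @param true_time ordinal true time/stage per cell (numeric or ordered
#'   labels coercible to numeric rank).
#' @param true_branch optional branch label per cell.
#' @param start_group optional label of the starting population.
#' @return An object of class `trajectory_truth`.
#' @export
trajectory_truth <- function(true_time, true_branch = NULL,
                             start_group = NULL) {
  true_time <- as.numeric(true_time)
  if (any(is.na(true_time))) stop("true_time must be numeric/ordinal")
  structure(list(true_time = true_time, true_branch = true_branch,
                 start_group = start_group),
            class = "trajectory_truth")
}

as_true_time <- function(truth) {
  if (inherits(truth, "trajectory_truth")) truth$true_time
  else as.numeric(truth)
}

#' Spearman correlation of pseudotime with true time
#'
#' Spearman rank correlation (midrank ties) between inferred pseudotime and
#' the ground-truth time labels.
#'
#' @param pred_pseudotime numeric pseudotime per cell.
#' @param truth a [trajectory_truth()] or numeric true time vector.
#' @return Scalar in [-1, 1].
#' @export
pseudotime_scc <- function(pred_pseudotime, truth) {
  tt <- as_true_time(truth)
  if (length(pred_pseudotime) != length(tt)) stop("length mismatch")
  if (length(tt) < 3L) stop("need at least 3 cells")
  if (length(unique(tt)) < 2L) stop("true time is constant")
  if (length(unique(pred_pseudotime)) < 2L)
    stop("predicted pseudotime is constant; correlation undefined")
  stats::cor(pred_pseudotime, tt, method = "spearman")
}

#' Pseudo-temporal ordering score
#'
#' Pairwise concordance between predicted and true cell order: over all cell
#' pairs with different true time labels, +1 when the predicted pseudotime
#' orders the pair like the truth, -1 when reversed, 0 when the prediction
#' ties; the score is the mean over comparable pairs. Perfect ordering
#' scores 1, a fully reversed ordering -1, an uninformative (all-tied)
#' prediction 0.
#'
#' @inheritParams pseudotime_scc
#' @return Scalar in [-1, 1].
#' @export
pseudotime_pos <- function(pred_pseudotime, truth) {
  tt <- as_true_time(truth)
  if (length(pred_pseudotime) != length(tt)) stop("length mismatch")
  pairs <- utils::combn(length(tt), 2L)
  dt <- tt[pairs[1L, ]] - tt[pairs[2L, ]]
  comparable <- dt != 0
  if (!any(comparable)) stop("no cell pairs with different true times")
  dp <- pred_pseudotime[pairs[1L, ]] - pred_pseudotime[pairs[2L, ]]
  sum(sign(dt[comparable]) * sign(dp[comparable])) / sum(comparable)
}

#' Match predicted to true branches and score the matching
#'
#' Each predicted branch is mapped to the true branch containing the largest
#' share of its cells (overlap measured as the fraction of the true branch
#' recovered; ties broken by the larger true branch, then label order).
#' Reports per-pair true overlap rates, the trajectory false rate (average
#' over matched pairs of the fraction of the matched true branch's cells
#' found in other predicted branches), and the incorrect cell type
#' proportion (average fraction of a matched predicted branch's cells not
#' belonging to its matched true branch). A perfect prediction scores
#' overlap 1, false rate 0, incorrect proportion 0. Note branches may share
#' cells (a progenitor population belongs to every lineage passing through
#' it), so `pred_branches`/`true_branch` may also be given as lists of
#' cell-id vectors.
#'
#' @param pred_branches predicted branch label per cell, or a list of
#'   character vectors of cell ids (one per predicted branch).
#' @param truth a [trajectory_truth()] with `true_branch` set, or a vector /
#'   list in the same formats as `pred_branches`.
#' @return List of class `branch_match`: `mapping` (data.frame with
#'   predicted branch, matched true branch, `true_overlap_rate`),
#'   `trajectory_false_rate`, `incorrect_cell_type_proportion`.
#' @export
match_branches <- function(pred_branches, truth) {
  tb <- if (inherits(truth, "trajectory_truth")) truth$true_branch else truth
  if (is.null(tb)) stop("truth has no branch labels")
  pred_sets <- as_branch_sets(pred_branches)
  true_sets <- as_branch_sets(tb)
  if (!length(pred_sets) || !length(true_sets)) stop("empty branches")

  true_sizes <- lengths(true_sets)
  mapping <- data.frame(pred = names(pred_sets), true = NA_character_,
                        true_overlap_rate = NA_real_,
                        stringsAsFactors = FALSE)
  incorrect <- numeric(length(pred_sets))
  for (i in seq_along(pred_sets)) {
    ov <- vapply(true_sets,
                 function(ts) length(intersect(pred_sets[[i]], ts)),
                 numeric(1))
    rate <- ov / true_sizes
    # largest overlap rate; ties -> larger true branch, then label order
    ord <- order(-rate, -true_sizes, names(true_sets))
    best <- ord[1L]
    mapping$true[i] <- names(true_sets)[best]
    mapping$true_overlap_rate[i] <- rate[best]
    incorrect[i] <- 1 - ov[best] / length(pred_sets[[i]])
  }
  false_rates <- vapply(seq_along(pred_sets), function(i) {
    ts <- true_sets[[mapping$true[i]]]
    others <- unique(unlist(pred_sets[-i]))
    length(intersect(ts, others)) / length(ts)
  }, numeric(1))
  structure(list(mapping = mapping,
                 trajectory_false_rate = mean(false_rates),
                 incorrect_cell_type_proportion = mean(incorrect)),
            class = "branch_match")
}

# coerce a per-cell label vector or a list of cell-id sets to a named list
as_branch_sets <- function(x) {
  if (length(x) == 0L) return(structure(list(), names = character(0)))
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("branch", seq_along(x))
    return(lapply(x, as.character))
  }
  x <- as.character(x)
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  split(ids, x)
}
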