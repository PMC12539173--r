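#' Simulation parameters for the gamma-Poisson single-cell generator
#'
#' Defaults emulate the statistical structure of the widely used Splatter
#' simulator at its default settings: gene base means are Gamma distributed,
#' library sizes log-normal, each group up-/down-regulates a random subset
#' of genes by log-normal factors, emission is Poisson, and technical
#' dropout zeroes observed counts with a logistic probability decreasing in
#' expression.
#'
#' @param n_genes number of genes D (default 10000).
#' @param n_cells number of cells N (default 1500).
#' @param group_proportions probability vector over groups (must sum to 1);
#'   default three equal groups.
#' @param mean_shape,mean_rate gamma hyperparameters of gene base means
#'   (default 0.6, 0.3).
#' @param libsize_logmean,libsize_logsd log-normal library-size parameters
#'   (default 11, 0.2).
#' @param de_prob probability a gene is differentially expressed in a group
#'   (default 0.1).
#' @param de_factor_logmean,de_factor_logsd log-normal magnitude of DE
#'   factors (default 0.1, 0.4); direction up/down equiprobable.
#' @param dropout_midpoint,dropout_shape logistic dropout curve applied to
#'   `log(mu_ij + 1)` (default 0, -1): the probability an entry is zeroed is
#'   `plogis(shape * (log(mu + 1) - midpoint))`, so negative shapes drop
#'   low-expression entries preferentially.
#' @param dropout logical, apply dropout (default TRUE).
#' @param seed integer master seed; each generation stage draws from its own
#'   derived substream so that e.g. changing `n_cells` does not perturb the
#'   gene-level draws.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 10000L, n_cells = 1500L,
                       group_proportions = c(1, 1, 1) / 3,
                       mean_shape = 0.6, mean_rate = 0.3,
                       libsize_logmean = 11, libsize_logsd = 0.2,
                       de_prob = 0.1,
                       de_factor_logmean = 0.1, de_factor_logsd = 0.4,
                       dropout_midpoint = 0, dropout_shape = -1,
                       dropout = TRUE, seed = 1L) {
  stopifnot(n_genes >= 2, n_cells >= 2,
            abs(sum(group_proportions) - 1) < 1e-8,
            all(group_proportions > 0),
            mean_shape > 0, mean_rate > 0, libsize_logsd >= 0,
            de_prob >= 0, de_prob <= 1, de_factor_logsd >= 0)
  structure(as.list(environment()), class = "sim_params")
}

# substream seeds derived from the master seed, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + stage
}

#' Simulate a grouped single-cell count matrix with ground truth
#'
#' Gene base means `lambda_i ~ Gamma(shape, rate)`; per group, genes are DE
#' with probability `de_prob` and multiply their mean by a log-normal factor
#' (inverted for down-regulation). The expected count of gene i in cell j of
#' group g is `mu_ij = L_j * lambda_i f_ig / sum_k lambda_k f_kg` with
#' library size `L_j` log-normal, and the observed count is Poisson. When
#' dropout is enabled each positive entry is zeroed independently with the
#' logistic probability described in [sim_params()]; the pre-dropout matrix
#' is returned alongside so the simulation ground truth ("True" baseline) is
#' exactly recoverable.
#'
#' @param p a [sim_params()].
#' @return List with `counts` (post-dropout [count_matrix()]), and `truth`:
#'   `group` (factor per cell), `de_factors` (genes x groups matrix, 1 for
#'   non-DE), `de_genes` (per group, data.frame of DE genes and factors),
#'   `dropped` (sparse logical genes x cells mask), `no_dropout_counts`
#'   (pre-dropout [count_matrix()]), `library_sizes`.
#' @export
simulate_counts <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  D <- as.integer(p$n_genes); N <- as.integer(p$n_cells)
  G <- length(p$group_proportions)
  gene_ids <- sprintf("gene%d", seq_len(D))
  cell_ids <- sprintf("cell%d", seq_len(N))

  set.seed(stage_seed(p$seed, 1L))
  lambda <- stats::rgamma(D, shape = p$mean_shape, rate = p$mean_rate)
  lambda[lambda < 1e-8] <- 1e-8

  set.seed(stage_seed(p$seed, 2L))
  fac <- matrix(1, D, G, dimnames = list(gene_ids, paste0("group", 1:G)))
  for (g in seq_len(G)) {
    is_de <- stats::runif(D) < p$de_prob
    f <- exp(stats::rnorm(D, p$de_factor_logmean, p$de_factor_logsd))
    up <- stats::runif(D) < 0.5
    f <- ifelse(up, f, 1 / f)
    fac[is_de, g] <- f[is_de]
  }

  set.seed(stage_seed(p$seed, 3L))
  group <- factor(sample(colnames(fac), N, replace = TRUE,
                         prob = p$group_proportions),
                  levels = colnames(fac))
  libsize <- stats::rlnorm(N, p$libsize_logmean, p$libsize_logsd)

  set.seed(stage_seed(p$seed, 4L))
  counts <- matrix(0L, D, N, dimnames = list(gene_ids, cell_ids))
  mu <- matrix(0, D, N)
  for (g in seq_len(G)) {
    cells <- which(group == colnames(fac)[g])
    if (!length(cells)) next
    base <- lambda * fac[, g]
    base <- base / sum(base)
    mu_g <- outer(base, libsize[cells])
    counts[, cells] <- stats::rpois(length(mu_g), mu_g)
    mu[, cells] <- mu_g
  }

  no_dropout <- count_matrix(counts, gene_ids, cell_ids)
  dropped <- NULL
  if (p$dropout) {
    set.seed(stage_seed(p$seed, 5L))
    pdrop <- stats::plogis(p$dropout_shape * (log(mu + 1) -
                                                p$dropout_midpoint))
    zap <- (matrix(stats::runif(length(mu)), D, N) < pdrop) & counts > 0
    counts[zap] <- 0L
    dropped <- methods::as(Matrix::Matrix(zap, sparse = TRUE), "CsparseMatrix")
    dimnames(dropped) <- list(gene_ids, cell_ids)
  }
  observed <- count_matrix(counts, gene_ids, cell_ids)

  de_genes <- lapply(colnames(fac), function(g) {
    de <- which(fac[, g] != 1)
    data.frame(gene = gene_ids[de], factor = fac[de, g],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(de_genes) <- colnames(fac)

  list(counts = observed,
       truth = list(group = stats::setNames(group, cell_ids),
                    de_factors = fac, de_genes = de_genes,
                    dropped = dropped, no_dropout_counts = no_dropout,
                    library_sizes = stats::setNames(libsize, cell_ids),
                    params = p))
}

#' Spike in degraded (zero-inflated) copies of a cell population
#'
#' Emulates low-quality cells: a fraction of the cells of one type are
#' copied, a fresh uniform random subset of genes is zeroed in each copy,
#' and the copies are appended as new cells labeled `"<type>-zero"`. The
#' original columns are untouched, so downstream separation of originals
#' from their degraded copies can be scored against ground truth.
#'
#' @param X a [count_matrix()].
#' @param labels cell-type label per cell (named by cell id or in column
#'   order).
#' @param target_type label of the population to degrade.
#' @param cell_fraction fraction of target cells to copy (default 0.10).
#' @param zero_fraction fraction of genes zeroed per copy (default 0.60).
#' @param seed integer seed.
#' @return List with `counts` (augmented `count_matrix`) and `labels`
#'   (augmented label vector; copies labeled `"<target_type>-zero"`).
#' @export
spike_degraded <- function(X, labels, target_type, cell_fraction = 0.10,
                           zero_fraction = 0.60, seed = 1L) {
  stopifnot(inherits(X, "count_matrix"),
            cell_fraction > 0, cell_fraction < 1,
            zero_fraction > 0, zero_fraction < 1)
  labels <- as.character(labels)
  if (length(labels) != ncol(X$values)) stop("one label per cell required")
  idx_type <- which(labels == target_type)
  if (!length(idx_type)) stop("target_type not present: ", target_type)
  n_copy <- round(cell_fraction * length(idx_type))
  if (n_copy < 1L) stop("cell_fraction selects fewer than one cell")
  set.seed(stage_seed(seed, 7L))
  picked <- sample(idx_type, n_copy)
  D <- nrow(X$values)
  n_zero <- round(zero_fraction * D)
  copies <- as.matrix(X$values[, picked, drop = FALSE])
  for (j in seq_len(n_copy)) copies[sample.int(D, n_zero), j] <- 0
  new_ids <- paste0(X$cell_ids[picked], "-zero")
  aug <- cbind(X$values, Matrix::Matrix(copies, sparse = TRUE))
  colnames(aug) <- c(X$cell_ids, new_ids)
  list(counts = count_matrix(aug, X$gene_ids, c(X$cell_ids, new_ids)),
       labels = stats::setNames(c(labels, rep(paste0(target_type, "-zero"),
                                              n_copy)),
                                c(X$cell_ids, new_ids)))
}

#' Ground-truth marker and non-marker panels from a simulation
#'
#' Ranks genes by the absolute log ratio of their DE factors between two
#' groups and returns the top `n_top` as true markers, plus `n_null` genes
#' differentially expressed in neither group as a known-negative panel for
#' false-positive estimation. The two lists are disjoint by construction.
#'
#' @param truth the `truth` component of [simulate_counts()].
#' @param group_a,group_b group names to contrast.
#' @param n_top number of top true markers (default 10).
#' @param n_null number of null genes to sample (default 50).
#' @param seed integer seed for the null sample.
#' @return List with `markers` (data.frame: gene, log_factor_ratio, ordered
#'   by decreasing magnitude) and `null_genes` (character vector).
#' @export
select_truth_markers <- function(truth, group_a, group_b, n_top = 10L,
                                 n_null = 50L, seed = 1L) {
  fac <- truth$de_factors
  stopifnot(all(c(group_a, group_b) %in% colnames(fac)))
  lr <- log(fac[, group_a] / fac[, group_b])
  de <- which(lr != 0)
  if (length(de) < n_top)
    stop("only ", length(de), " DE genes between groups; need ", n_top)
  ord <- de[order(-abs(lr[de]), rownames(fac)[de])]
  markers <- data.frame(gene = rownames(fac)[ord[seq_len(n_top)]],
                        log_factor_ratio = lr[ord[seq_len(n_top)]],
                        row.names = NULL, stringsAsFactors = FALSE)
  null_pool <- rownames(fac)[fac[, group_a] == 1 & fac[, group_b] == 1]
  if (length(null_pool) < n_null)
    stop("only ", length(null_pool), " non-DE genes; need ", n_null)
  set.seed(stage_seed(seed, 8L))
  list(markers = markers, null_genes = sample(null_pool, n_null))
}
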