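#' Cluster cells on their principal-component scores
#'
#' Delegates to standard algorithms; clustering itself is not the point of
#' this package, but the downstream evaluation needs a reproducible labeller
#' with the number of clusters fixed to the number of known cell-type labels.
#'
#' \describe{
#'   \item{kmeans}{`stats::kmeans` with 10 random restarts, seeded.}
#'   \item{graph}{shared-nearest-neighbour graph (Jaccard-weighted, 10
#'     neighbours) with Walktrap community detection cut at exactly
#'     `n_clusters` communities. Walktrap is used rather than Louvain
#'     because its hierarchy can be cut at a prescribed number of clusters.}
#' }
#'
#' @param E an `embedding_result` (or a plain cells x k score matrix).
#' @param n_clusters number of clusters (>= 2, or `n_cells` for the
#'   degenerate all-singletons case).
#' @param algorithm `"kmeans"` (default) or `"graph"`.
#' @param seed integer seed.
#' @param n_neighbours neighbourhood size for the graph route.
#' @return Integer vector of labels in 0..K-1, named by cell id.
#' @export
cluster_cells <- function(E, n_clusters, algorithm = c("kmeans", "graph"),
                          seed = 1L, n_neighbours = 10L) {
  algorithm <- match.arg(algorithm)
  S <- if (inherits(E, "embedding_result")) E$scores else as.matrix(E)
  n <- nrow(S)
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n < n_clusters) stop("fewer cells than clusters")
  if (n_clusters == n) {
    labels <- seq_len(n) - 1L
  } else if (algorithm == "kmeans") {
    set.seed(seed)
    labels <- stats::kmeans(S, centers = n_clusters, nstart = 10L,
                            iter.max = 100L)$cluster - 1L
  } else {
    g <- snn_graph(S, k = min(n_neighbours, n - 1L))
    set.seed(seed)
    wt <- igraph::cluster_walktrap(g)
    labels <- tryCatch(igraph::cut_at(wt, no = n_clusters) - 1L,
                       error = function(e) igraph::membership(wt) - 1L)
  }
  stats::setNames(as.integer(labels), rownames(S))
}

# shared-nearest-neighbour graph with Jaccard edge weights
snn_graph <- function(S, k = 10L) {
  d <- as.matrix(stats::dist(S))
  n <- nrow(d)
  nn <- t(apply(d, 1L, function(r) order(r)[2:(k + 1L)]))
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), k), as.vector(nn))] <- TRUE
  shared <- tcrossprod(adj * 1)
  ksize <- rowSums(adj)
  jac <- shared / (outer(ksize, ksize, "+") - shared)
  jac[shared == 0] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}
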