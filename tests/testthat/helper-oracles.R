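# Fixture generators and independent brute-force oracles used across tests.

# random sparse integer count matrix with no all-zero cells
rand_counts <- function(D, N, sparsity = 0.7, lambda = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rpois(D * N, lambda), D, N)
  m[matrix(stats::runif(D * N) < sparsity, D, N)] <- 0L
  empty <- colSums(m) == 0
  m[1L, empty] <- 1L
  count_matrix(m)
}

# CLR by the definition: dense closure then log over geometric mean
oracle_clr <- function(X, delta) {
  m <- as.matrix(X$values)
  m <- sweep(m, 2L, delta, "+")
  apply(m, 2L, function(col) log(col) - mean(log(col)))
}

# ILR pivot coordinates by direct double-loop evaluation of the formula
oracle_ilr <- function(X, delta) {
  m <- sweep(as.matrix(X$values), 2L, delta, "+")
  D <- nrow(m)
  out <- matrix(0, D - 1L, ncol(m))
  for (j in seq_len(ncol(m))) for (i in seq_len(D - 1L)) {
    gm_tail <- exp(mean(log(m[(i + 1L):D, j])))
    out[i, j] <- sqrt((D - i) / (D - i + 1)) * log(m[i, j] / gm_tail)
  }
  out
}

# Rand index adjustment by explicit enumeration of all cell pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- same_b <- both <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    same_a <- same_a + sa; same_b <- same_b + sb; both <- both + (sa && sb)
  }
  npairs <- n * (n - 1) / 2
  expected <- same_a * same_b / npairs
  maxi <- (same_a + same_b) / 2
  (both - expected) / (maxi - expected)
}

# NMI by explicit loops over label values
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  ent <- function(l, u) -sum(sapply(u, function(x) {
    p <- sum(l == x) / n
    if (p > 0) p * log(p) else 0
  }))
  2 * mi / (ent(a, ua) + ent(b, ub))
}

# entropy of accuracy by explicit loops over predicted clusters
oracle_h_acc <- function(pred, truth) {
  cl <- unique(pred)
  tot <- 0
  for (i in cl) {
    inside <- truth[pred == i]
    for (g in unique(inside)) {
      p <- sum(inside == g) / length(inside)
      tot <- tot - p * log(p)
    }
  }
  tot / length(cl)
}

# AUROC by enumeration of positive x negative pairs
oracle_auc <- function(values, positive) {
  pos <- values[positive]; neg <- values[!positive]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

lr_values <- function(M) M$values
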