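test_that("count_matrix enforces its invariants", {
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  X <- count_matrix(m, c("g1", "g2"), c("c1", "c2"))
  expect_s3_class(X, "count_matrix")
  expect_identical(dim(X), c(2L, 2L))
  expect_error(count_matrix(matrix(-1, 1, 1)), "non-negative")
  expect_error(count_matrix(matrix(1.5, 1, 1)), "integral")
  expect_error(count_matrix(m, c("g", "g"), c("c1", "c2")), "unique")
  expect_error(count_matrix(m, "g1", c("c1", "c2")), "length")
})

test_that("cell offsets match the scheme definitions", {
  X <- count_matrix(matrix(c(100, 400), 1, 2))
  expect_equal(unname(compute_cell_offsets(X, addition_scheme("SMAX"))),
               c(0.25, 1.0))
  expect_equal(unname(compute_cell_offsets(X, addition_scheme("SGM"))),
               c(0.5, 2.0))
  X2 <- count_matrix(matrix(20000, 1, 1))
  expect_equal(unname(compute_cell_offsets(X2, addition_scheme("S10000"))), 2)
  expect_equal(unname(compute_cell_offsets(X, addition_scheme("CONSTANT", 1))),
               c(1, 1))
  # invariants on random totals: SMAX max is 1, SGM geometric mean is 1
  for (s in 1:5) {
    X3 <- rand_counts(30, 25, seed = s)
    expect_equal(max(compute_cell_offsets(X3, addition_scheme("SMAX"))), 1)
    expect_equal(exp(mean(log(compute_cell_offsets(X3,
                                                   addition_scheme("SGM"))))),
                 1, tolerance = 1e-12)
  }
  expect_error(addition_scheme("CONSTANT", -1), "positive")
  Z <- count_matrix(matrix(c(1, 0), 1, 2))
  expect_error(compute_cell_offsets(Z, addition_scheme("SGM")), "cell2")
})

test_that("clr matches the worked example and the dense oracle", {
  X1 <- count_matrix(matrix(c(0, 1, 3), 3, 1))
  got <- clr(X1, addition_scheme("CONSTANT", 1))$values
  expect_equal(unname(got[, 1]), c(-log(2), 0, log(2)), tolerance = 1e-12)

  for (s in 1:5) {
    X <- rand_counts(40, 15, seed = 10 + s)
    for (kind in c("CONSTANT", "S10000", "SMAX", "SGM")) {
      sch <- addition_scheme(kind)
      delta <- compute_cell_offsets(X, sch)
      expect_equal(unname(clr(X, sch)$values),
                   unname(oracle_clr(X, delta)), tolerance = 1e-12)
    }
  }
})

test_that("clr zero-sum, scale invariance, and permutation invariance hold", {
  for (s in 1:10) {
    X <- rand_counts(50, 20, seed = 20 + s)
    C <- clr(X, addition_scheme("SGM"))$values
    expect_lt(max(abs(colSums(C))), 1e-8 * nrow(C))
    # S10000 offsets scale with the totals, so uniform count scaling cancels
    X4 <- count_matrix(X$values * 4L, X$gene_ids, X$cell_ids)
    expect_equal(clr(X4, addition_scheme("S10000"))$values,
                 clr(X, addition_scheme("S10000"))$values, tolerance = 1e-10)
    # constant scheme: scaling counts and the constant together cancels too
    expect_equal(clr(X4, addition_scheme("CONSTANT", 4))$values,
                 clr(X, addition_scheme("CONSTANT", 1))$values,
                 tolerance = 1e-10)
    # permuting genes permutes rows identically
    perm <- sample(X$gene_ids)
    Xp <- subset_counts(X, genes = perm)
    expect_equal(clr(Xp, addition_scheme("SGM"))$values, C[perm, ],
                 tolerance = 1e-12)
  }
})

test_that("clr denominator uses all genes even for a gene subset", {
  X <- rand_counts(60, 12, seed = 31)
  full <- clr(X, addition_scheme("SGM"))
  sub <- clr(X, addition_scheme("SGM"), genes_out = X$gene_ids[5:10])
  expect_identical(dim(sub$values), c(6L, 12L))
  expect_equal(sub$values, full$values[X$gene_ids[5:10], ])
  expect_error(clr(X, genes_out = "nope"), "unknown genes")
})

test_that("clr with genes_out does not materialize the dense matrix", {
  X <- rand_counts(50000, 400, sparsity = 0.99, seed = 32)
  gc(reset = TRUE)
  sub <- clr(X, addition_scheme("SGM"), genes_out = X$gene_ids[1:10])
  peak_mb <- sum(gc()[, 6L])
  base_mb <- sum(gc(reset = TRUE)[, 6L])
  # dense 50000 x 400 would need ~160 MB; the subset path stays far below
  expect_lt(peak_mb - base_mb, 120)
  expect_identical(dim(sub$values), c(10L, 400L))
})

test_that("ilr matches its formula, is isometric with clr, and needs D >= 2", {
  X1 <- count_matrix(matrix(c(1, 0), 2, 1))
  got <- ilr(X1, addition_scheme("CONSTANT", 1))$values
  expect_equal(unname(got[, 1]), sqrt(1 / 2) * log(2), tolerance = 1e-12)

  for (s in 1:5) {
    X <- rand_counts(10, 8, seed = 40 + s)
    sch <- addition_scheme("SGM")
    delta <- compute_cell_offsets(X, sch)
    I <- ilr(X, sch)$values
    expect_identical(nrow(I), nrow(X$values) - 1L)
    expect_equal(unname(I), oracle_ilr(X, delta), tolerance = 1e-10)
    C <- clr(X, sch)$values
    expect_equal(unname(sqrt(colSums(I^2))), unname(sqrt(colSums(C^2))),
                 tolerance = 1e-8)
    # permutation leaves per-cell norms (Aitchison geometry) unchanged
    Xp <- subset_counts(X, genes = sample(X$gene_ids))
    expect_equal(colSums(ilr(Xp, sch)$values^2), colSums(I^2),
                 tolerance = 1e-8)
  }
  # constant composition maps to the origin
  Xc <- count_matrix(matrix(3L, 5, 2))
  expect_equal(max(abs(ilr(Xc, addition_scheme("CONSTANT", 1))$values)), 0)
  expect_error(ilr(count_matrix(matrix(1, 1, 1))), "at least 2")
})

test_that("hkglr centers on the housekeeping panel", {
  X <- rand_counts(30, 10, seed = 50)
  # panel = all genes coincides with clr
  H <- hkglr(X, addition_scheme("SGM"), hkg = X$gene_ids)
  expect_equal(H$values, clr(X, addition_scheme("SGM"))$values,
               tolerance = 1e-12)
  # panel rows of the output average to zero per cell
  panel <- X$gene_ids[c(2, 7, 11, 20, 28)]
  H5 <- hkglr(X, addition_scheme("SGM"), hkg = panel)
  expect_lt(max(abs(colMeans(H5$values[panel, ]))), 1e-12)
  expect_error(hkglr(X, hkg = c("SDHA", "nope")), "SDHA")
  expect_error(hkglr(X, hkg = character(0)), "non-empty")
})

test_that("lognormalize matches its formula and preserves sparsity", {
  X <- count_matrix(matrix(c(9, 9991), 2, 1))
  LN <- lognormalize(X)
  expect_equal(LN$values[1, 1], log(10), tolerance = 1e-12)
  X0 <- rand_counts(30, 10, seed = 60)
  LN0 <- lognormalize(X0)
  expect_identical(as.vector(X0$values == 0), as.vector(LN0$values == 0))
  # per-cell scaling cancels
  X2 <- count_matrix(X0$values %*% Matrix::Diagonal(10, rep(3, 10)),
                     X0$gene_ids, X0$cell_ids)
  expect_equal(as.matrix(lognormalize(X2)$values), as.matrix(LN0$values),
               tolerance = 1e-12)
  expect_error(lognormalize(X0, scale_factor = 0), "positive")
})

test_that("clr_from_lognorm reproduces the count-addition clr exactly", {
  for (s in 1:10) {
    X <- rand_counts(50, 20, seed = 70 + s)
    via_ln <- clr_from_lognorm(lognormalize(X))
    direct <- clr(X, addition_scheme("S10000"))
    expect_equal(via_ln$values, direct$values, tolerance = 1e-10)
  }
  # centering identity and degenerate cases
  X <- rand_counts(20, 6, seed = 81)
  LN <- lognormalize(X)
  ctr <- X$gene_ids[1:7]
  out <- clr_from_lognorm(LN, genes_center = ctr)
  expect_lt(max(abs(colMeans(out$values[ctr, ]))), 1e-12)
  expect_error(clr_from_lognorm(LN, genes_center = character(0)), "empty")
  flat <- matrix(2.5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(max(abs(clr_from_lognorm(flat)$values)), 0)
})

test_that("half-minimum scheme only offsets zeros and is exposed", {
  X <- count_matrix(matrix(c(0, 2, 6, 0, 4, 4), 3, 2))
  sch <- addition_scheme("HALFMIN")
  delta <- compute_cell_offsets(X, sch)
  expect_equal(unname(delta), c(1, 2))
  C <- clr(X, sch)$values
  m <- as.matrix(X$values)
  m[m == 0] <- rep(delta, each = 3)[as.matrix(X$values) == 0]
  expect_equal(unname(C),
               unname(apply(m, 2, function(col) log(col) - mean(log(col)))),
               tolerance = 1e-12)
})
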