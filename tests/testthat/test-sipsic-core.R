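test_that("top-tau window size follows ceil with floor of one", {
  expect_identical(top_tau_count(100, 5), 5L)
  expect_identical(top_tau_count(3, 5), 1L)
  expect_identical(top_tau_count(1000, 2), 20L)
  expect_identical(top_tau_count(6, 5), 1L)
  expect_identical(top_tau_count(41, 5), 3L) # ceil(2.05)
  expect_error(top_tau_count(100, 0), "tau")
  expect_error(top_tau_count(100, 101), "tau")
})

test_that("normalization factor is top-tau median with maximum fallback", {
  expect_equal(normalization_factor(c(rep(0, 95), 1, 2, 3, 4, 5), tau = 5), 3)
  expect_equal(normalization_factor(rep(0, 40), tau = 5), 0)
  # zero median in the top-5 window -> fall back to the gene maximum
  expect_equal(normalization_factor(c(rep(0, 99), 7), tau = 5), 7)
  # even window: median is the mean of the two central order statistics
  expect_equal(normalization_factor(c(10, 4, 0, 0), tau = 50), 7)
})

test_that("per-gene factors match the vector kernel on sparse and dense", {
  set.seed(11)
  x <- random_expression_matrix(40, 60, density = 0.3)
  xs <- expression_matrix(Matrix::Matrix(unclass(x), sparse = TRUE), unit = "CPM")
  for (tau in c(2, 5, 10, 50)) {
    nf_dense <- norm_factors(x, tau = tau)
    nf_ref <- vapply(rownames(x), function(g) normalization_factor(x[g, ], tau),
                     numeric(1))
    expect_equal(as.numeric(nf_dense), unname(nf_ref), tolerance = 1e-15)
    expect_equal(as.numeric(norm_factors(xs, tau = tau)), unname(nf_ref),
                 tolerance = 1e-15)
  }
})

test_that("gene normalization divides by factors and zeroes dead genes", {
  x <- expression_matrix(rbind(A = c(1, 2, 3), B = c(0, 0, 0)),
                         unit = "CPM", cell_ids = paste0("c", 1:3))
  nf <- c(A = 3, B = 0)
  s <- normalize_genes(x, nf)
  expect_equal(unname(s["A", ]), c(1, 2, 3) / 3)
  expect_equal(unname(s["B", ]), c(0, 0, 0))
  expect_false(anyNA(s))
})

test_that("rank weights ascend with total expression and use midranks", {
  x <- expression_matrix(rbind(A = c(1, 2, 3), B = c(0, 1, 6)),
                         unit = "CPM", cell_ids = paste0("c", 1:3))
  rw <- rank_weights(x, c("A", "B"))
  expect_equal(rw$ranks, c(A = 1, B = 2))

  xt <- expression_matrix(rbind(A = c(3, 3), B = c(2, 4)),
                          unit = "CPM", cell_ids = c("c1", "c2"))
  expect_equal(rank_weights(xt, c("A", "B"))$ranks, c(A = 1.5, B = 1.5))

  set.seed(2)
  x2 <- random_expression_matrix(10, 8, density = 1)
  rw2 <- rank_weights(x2, rownames(x2))
  expect_setequal(rw2$ranks, 1:10)
  expect_equal(sum(rw2$ranks), 10 * 11 / 2)
  ord <- order(rw2$totals)
  expect_true(all(diff(rw2$ranks[ord]) >= 0))

  expect_error(rank_weights(x, c("NOPE1", "NOPE2"), set_name = "S"),
               "no genes in the matrix")
  expect_equal(rank_weights(x, c("A", "MISSING"))$genes_missing, "MISSING")
})

test_that("worked example scores are exactly 1/12, 1/4, 3/4", {
  x <- expression_matrix(rbind(A = c(1, 2, 3), B = c(0, 1, 6)),
                         unit = "CPM", cell_ids = paste0("c", 1:3))
  p <- score_pathway(x, c("A", "B"), tau = 5)
  expect_equal(as.numeric(p), c(1 / 12, 1 / 4, 3 / 4), tolerance = 1e-15)
  # weighted-mean denominator rescales by n^2 / (n(n+1)/2) = 4/3
  pw <- score_pathway(x, c("A", "B"), tau = 5, denominator = "weighted_mean")
  expect_equal(as.numeric(pw), c(1 / 12, 1 / 4, 3 / 4) * 4 / 3, tolerance = 1e-15)
})

test_that("scores match the brute-force oracle on random inputs", {
  set.seed(123)
  for (rep in 1:25) {
    n_genes <- sample(3:20, 1)
    n_cells <- sample(2:10, 1)
    x <- random_expression_matrix(n_genes, n_cells,
                                  density = runif(1, 0.2, 0.9))
    genes <- sample(rownames(x), sample(1:min(6, n_genes), 1))
    tau <- sample(c(2, 5, 10, 60), 1)
    p <- score_pathway(x, genes, tau = tau)
    expect_equal(as.numeric(p), as.numeric(oracle_score(x, genes, tau = tau)),
                 tolerance = 1e-12)
  }
})

test_that("sparse and dense scoring agree to 1e-12", {
  set.seed(9)
  x <- random_expression_matrix(30, 25, density = 0.3)
  xs <- expression_matrix(Matrix::Matrix(unclass(x), sparse = TRUE), unit = "CPM")
  genes <- sample(rownames(x), 8)
  expect_equal(as.numeric(score_pathway(xs, genes)),
               as.numeric(score_pathway(x, genes)), tolerance = 1e-12)
})

test_that("per-gene rescaling leaves scores unchanged when rank order holds", {
  set.seed(31)
  x <- random_expression_matrix(12, 10, density = 1)
  genes <- rownames(x)[1:6]
  p0 <- score_pathway(x, genes)
  # scale factors near 1: total-expression order is preserved
  sc <- runif(nrow(x), 0.99, 1.01)
  ord0 <- order(Matrix::rowSums(x[genes, ]))
  x2 <- expression_matrix(unclass(x) * sc, unit = "CPM")
  ord1 <- order(Matrix::rowSums(x2[genes, ]))
  expect_identical(ord0, ord1) # property is only claimed for equal order
  expect_equal(as.numeric(score_pathway(x2, genes)), as.numeric(p0), tolerance = 1e-12)
})

test_that("dominance, nonnegativity, and single-gene symmetry hold", {
  set.seed(17)
  x <- random_expression_matrix(15, 12, density = 0.5)
  p <- score_pathway(x, rownames(x)[1:5])
  expect_true(all(is.finite(p)) && all(p >= 0))

  # cell dominating another elementwise never scores lower
  m <- unclass(x)
  m[, 2] <- m[, 1] + 1
  x2 <- expression_matrix(m, unit = "CPM")
  p2 <- score_pathway(x2, rownames(x2)[1:5])
  expect_gte(p2[2], p2[1])

  # single-gene set with constant expression scores 1 everywhere
  xc <- expression_matrix(matrix(4, 1, 10, dimnames = list("A", paste0("c", 1:10))),
                          unit = "CPM")
  expect_equal(as.numeric(score_pathway(xc, "A")), rep(1, 10))
})

test_that("collection scoring equals per-set scoring and records skips", {
  set.seed(20)
  x <- random_expression_matrix(30, 15, density = 0.4)
  sets <- list(S1 = rownames(x)[1:5], S2 = rownames(x)[c(4, 9, 12)],
               S3 = c("ABSENT1", "ABSENT2"))
  expect_warning(sc <- score_collection(x, sets), "skipping 1")
  expect_equal(rownames(sc), c("S1", "S2"))
  meta <- attr(sc, "meta")
  expect_true(meta$skipped[meta$set == "S3"])
  for (nm in c("S1", "S2")) {
    expect_equal(sc[nm, ], score_pathway(x, sets[[nm]]), tolerance = 1e-14,
                 ignore_attr = TRUE)
  }
  expect_error(suppressWarnings(score_collection(x, list(S = "NOPE"))),
               "no gene set overlaps")
})

test_that("permuting cells permutes score columns identically", {
  set.seed(21)
  x <- random_expression_matrix(20, 12, density = 0.5)
  sets <- list(S1 = rownames(x)[1:6], S2 = rownames(x)[7:12])
  perm <- sample(ncol(x))
  xp <- expression_matrix(unclass(x)[, perm], unit = "CPM")
  s1 <- score_collection(x, sets)
  s2 <- score_collection(xp, sets)
  expect_equal(s2[, colnames(x)], s1, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("log-tagged matrices warn but still score", {
  x <- expression_matrix(rbind(A = c(1, 2, 3)), unit = "log",
                         cell_ids = paste0("c", 1:3))
  expect_warning(score_pathway(x, "A"), "linear TPM/CPM")
})
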