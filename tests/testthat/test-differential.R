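test_that("pooled t-test matches the closed form", {
  res <- t_test_pathway(c(1, 2, 3), c(4, 5, 6))
  # pooled sd 1, se = sqrt(2/3), df = 4
  expect_equal(res$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(res$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(res$median_diff, -3)
})

test_that("t-test symmetry, antisymmetry, and degenerate variance rules", {
  a <- c(1, 2, 5, 3)
  same <- t_test_pathway(a, a)
  expect_equal(same$t_stat, 0)
  expect_equal(same$median_diff, 0)

  b <- c(0, 4, 1, 1)
  fwd <- t_test_pathway(a, b)
  rev <- t_test_pathway(b, a)
  expect_equal(fwd$t_stat, -rev$t_stat)
  expect_equal(fwd$median_diff, -rev$median_diff)
  expect_equal(fwd$p_value, rev$p_value)

  expect_equal(t_test_pathway(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(t_test_pathway(c(2, 2), c(3, 3)), "zero variance")
  expect_error(t_test_pathway(1, c(1, 2)), "at least 2")
})

test_that("Welch variant differs from pooled on heteroskedastic input", {
  a <- c(1, 1.1, 0.9, 1.05)
  b <- c(2, 6, -1, 4, 3, 7)
  expect_false(isTRUE(all.equal(t_test_pathway(a, b)$p_value,
                                t_test_pathway(a, b, var_equal = FALSE)$p_value)))
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

# Deterministic 3-group score fixture: pathway PA separates g1 from g2
# strongly but overlaps g3; PB separates nothing.
three_group_fixture <- function() {
  set.seed(77)
  n <- 30
  cells <- sprintf("c%02d", 1:(3 * n))
  groups <- setNames(rep(c("g1", "g2", "g3"), each = n), cells)
  pa <- c(rnorm(n, 5, 0.3), rnorm(n, 1, 0.3), rnorm(n, 5.02, 0.3))
  pb <- rnorm(3 * n, 2, 0.5)
  scores <- rbind(PA = pa, PB = pb)
  colnames(scores) <- cells
  list(scores = scores, groups = groups)
}

test_that("max-FDR rule: one non-significant pair forces ns", {
  fx <- three_group_fixture()
  res <- pairwise_analysis(fx$scores, fx$groups, fdr_threshold = 0.01)
  calls <- res$calls
  g1 <- calls[calls$pathway == "PA" & calls$group == "g1", ]
  expect_equal(g1$direction, "ns")
  # the reported max FDR is the non-significant g1-g3 pair's FDR
  pair13 <- res$pairs[res$pairs$pathway == "PA" &
                        res$pairs$group_a == "g1" & res$pairs$group_b == "g3", ]
  expect_equal(g1$max_fdr, pair13$fdr)
  expect_gt(g1$max_fdr, 0.01)
  # g2 is consistently below both others -> down call with max FDR < 0.01
  g2 <- calls[calls$pathway == "PA" & calls$group == "g2", ]
  expect_equal(g2$direction, "down")
  expect_lt(g2$max_fdr, 0.01)
  expect_equal(calls$direction[calls$pathway == "PB"], rep("ns", 3))
})

test_that("two-group analysis reduces to t-test plus BH", {
  set.seed(12)
  n <- 20
  cells <- sprintf("c%02d", 1:(2 * n))
  groups <- setNames(rep(c("a", "b"), each = n), cells)
  scores <- matrix(rnorm(5 * 2 * n), 5, 2 * n,
                   dimnames = list(paste0("P", 1:5), cells))
  scores[2, groups == "a"] <- scores[2, groups == "a"] + 2
  res <- pairwise_analysis(scores, groups, fdr_threshold = 0.01)

  p_manual <- vapply(rownames(scores), function(pw) {
    t_test_pathway(scores[pw, groups == "a"], scores[pw, groups == "b"])$p_value
  }, numeric(1))
  fdr_manual <- bh_fdr(p_manual)
  got <- res$pairs[match(rownames(scores), res$pairs$pathway), ]
  expect_equal(got$p_value, unname(p_manual), tolerance = 1e-12)
  expect_equal(got$fdr, unname(fdr_manual), tolerance = 1e-12)
  # with two groups max_fdr is just that pair's fdr
  ca <- res$calls[res$calls$group == "a", ]
  expect_equal(ca$max_fdr[match(rownames(scores), ca$pathway)],
               unname(fdr_manual), tolerance = 1e-12)
  expect_equal(ca$direction[ca$pathway == "P2"], "up")
})

test_that("calls are invariant to positive per-pathway rescaling", {
  fx <- three_group_fixture()
  shift <- abs(min(fx$scores)) + 0.1
  rescaled <- (fx$scores + shift) * c(13.7, 0.002)
  a <- pairwise_analysis(fx$scores, fx$groups)
  b <- pairwise_analysis(rescaled, fx$groups)
  expect_equal(a$calls$direction, b$calls$direction)
  expect_equal(a$calls$max_fdr, b$calls$max_fdr, tolerance = 1e-9)
})

test_that("small groups are excluded with a warning", {
  scores <- matrix(rnorm(30), 3, 10,
                   dimnames = list(paste0("P", 1:3), paste0("c", 1:10)))
  groups <- setNames(c(rep("a", 5), rep("b", 4), "c"), paste0("c", 1:10))
  expect_warning(res <- pairwise_analysis(scores, groups), "< 2 cells")
  expect_setequal(unique(res$calls$group), c("a", "b"))
  groups2 <- setNames(c(rep("a", 9), "b"), paste0("c", 1:10))
  expect_warning(expect_error(pairwise_analysis(scores, groups2), "at least 2 groups"))
})

test_that("label permutation on null scores keeps calls near nominal", {
  set.seed(99)
  n_path <- 50; n <- 40
  cells <- sprintf("c%02d", 1:n)
  scores <- matrix(rnorm(n_path * n), n_path, n,
                   dimnames = list(sprintf("P%02d", 1:n_path), cells))
  calls <- 0L; total <- 0L
  for (r in 1:20) {
    groups <- setNames(sample(rep(c("a", "b"), each = n / 2)), cells)
    res <- pairwise_analysis(scores, groups, fdr_threshold = 0.01)
    calls <- calls + sum(res$calls$direction != "ns") / 2 # two mirrored rows per pathway
    total <- total + n_path
  }
  expect_lte(calls / total, 0.02)
})
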