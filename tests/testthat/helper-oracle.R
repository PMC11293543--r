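# Independent brute-force oracle for the pathway score: explicit loops, no
# shared code with the package implementation.
oracle_score <- function(x, genes, tau = 5, denominator = "np2") {
  x <- as.matrix(x)
  genes <- unique(genes)
  genes <- genes[genes %in% rownames(x)]
  stopifnot(length(genes) > 0)
  n_cells <- ncol(x)
  k <- max(1, ceiling(tau / 100 * n_cells))

  nf <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    v <- sort(x[genes[gi], ], decreasing = TRUE)
    med <- median(v[1:k])
    nf[gi] <- if (med > 0) med else max(v)
  }
  s <- matrix(0, length(genes), n_cells)
  for (gi in seq_along(genes)) {
    for (j in seq_len(n_cells)) {
      s[gi, j] <- if (nf[gi] > 0) x[genes[gi], j] / nf[gi] else 0
    }
  }
  totals <- numeric(length(genes))
  for (gi in seq_along(genes)) totals[gi] <- sum(x[genes[gi], ])
  rk <- rank(totals, ties.method = "average")
  np <- length(genes)
  denom <- if (denominator == "np2") np^2 else np * (np + 1) / 2
  p <- numeric(n_cells)
  for (j in seq_len(n_cells)) {
    acc <- 0
    for (gi in seq_along(genes)) acc <- acc + rk[gi] * s[gi, j]
    p[j] <- acc / denom
  }
  setNames(p, colnames(x))
}

# Hand Benjamini-Hochberg: adj_(i) = min_{l >= i} p_(l) * m / l, input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_expression_matrix <- function(n_genes, n_cells, density = 0.5,
                                     unit = "CPM") {
  m <- matrix(0, n_genes, n_cells)
  nnz <- rbinom(1, n_genes * n_cells, density)
  idx <- sample(n_genes * n_cells, nnz)
  m[idx] <- round(rexp(nnz, rate = 0.1), 3)
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  expression_matrix(m, unit = unit)
}
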