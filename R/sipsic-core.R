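#' Number of cells in the top-tau% window
#'
#' The per-gene normalization factor is the median expression of the tau
#' percent of cells with highest expression. The window size is
#' `k = max(1, ceiling(tau/100 * n_cells))`: rounding up plus the floor of
#' one guarantees a nonempty window even for very small cell groups.
#'
#' @param n_cells number of cells (>= 1).
#' @param tau percentage in (0, 100].
#' @return integer window size `k`.
#' @examples
#' top_tau_count(100, 5) # 5
#' top_tau_count(3, 5)   # 1
#' @export
top_tau_count <- function(n_cells, tau = 5) {
  check_tau(tau)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  max(1L, as.integer(ceiling(tau / 100 * n_cells)))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0 || tau > 100) {
    stop("tau must be a percentage in (0, 100]", call. = FALSE)
  }
  invisible(tau)
}

#' Robust per-gene normalization factor
#'
#' The median of the gene's top-tau% cell values. Because scRNA-seq data are
#' sparse, this median is usually positive yet not an outlier; when it is
#' zero the gene's maximum value is used instead. An all-zero gene yields 0,
#' which downstream turns into an all-zero normalized row.
#'
#' @param values nonnegative expression values of one gene across cells.
#' @param tau percentage of highest-expressing cells in the window.
#' @return a single nonnegative normalization factor.
#' @examples
#' normalization_factor(c(rep(0, 95), 1:5), tau = 5) # median of top 5 = 3
#' @export
normalization_factor <- function(values, tau = 5) {
  check_tau(tau)
  n <- length(values)
  if (n == 0) stop("empty value vector", call. = FALSE)
  k <- top_tau_count(n, tau)
  nf_from_nonzeros(values[values != 0], n, k)
}

# Shared kernel: NF from a gene's nonzero values given the total cell count
# n and window size k. Implicit zeros fill the window when nonzeros < k.
nf_from_nonzeros <- function(nz, n, k) {
  m <- length(nz)
  if (m == 0) return(0)
  top <- if (m >= k) sort(nz, decreasing = TRUE)[seq_len(k)] else c(sort(nz, decreasing = TRUE), rep(0, k - m))
  med <- stats::median(top)
  if (med > 0) med else max(nz)
}

#' Normalization factors for every gene of a matrix
#'
#' @param x genes x cells nonnegative expression matrix.
#' @param tau percentage in (0, 100].
#' @return named numeric vector of per-gene factors; attributes `tau` and
#'   `k_top` record the window used.
#' @export
norm_factors <- function(x, tau = 5) {
  check_tau(tau)
  n <- ncol(x)
  k <- top_tau_count(n, tau)
  nz <- row_nonzeros(x)
  nf <- vapply(nz, nf_from_nonzeros, numeric(1), n = n, k = k)
  names(nf) <- rownames(x)
  attr(nf, "tau") <- tau
  attr(nf, "k_top") <- k
  nf
}

#' Normalized gene scores
#'
#' Divides each gene row by its normalization factor: `S[i, j] = X[i, j] /
#' NF[i]`. Rows with factor 0 (all-zero genes) become all-zero rather than
#' NaN. The sparsity pattern is preserved.
#'
#' @param x genes x cells expression matrix.
#' @param nf per-gene factors from [norm_factors()] computed on the same rows.
#' @return matrix of normalized gene scores, same class and dimnames as `x`.
#' @export
normalize_genes <- function(x, nf = norm_factors(x)) {
  if (length(nf) != nrow(x)) {
    stop("normalization factors do not match matrix rows", call. = FALSE)
  }
  inv <- ifelse(nf > 0, 1 / nf, 0)
  if (methods::is(x, "sparseMatrix")) {
    out <- Matrix::Diagonal(nrow(x), inv) %*% methods::as(x, "generalMatrix")
    out <- methods::as(out, "CsparseMatrix")
    dimnames(out) <- dimnames(x)
    out
  } else {
    out <- x * inv
    dimnames(out) <- dimnames(x)
    out
  }
}

#' Expression-rank weights for a gene set
#'
#' Genes of the set present in the matrix are ranked by their total
#' expression across all cells; the highest total receives the largest rank
#' (`n_set`), so highly expressed genes -- which carry more information in
#' sparse data -- get the largest weights. Ties receive midranks, making the
#' weights independent of gene order.
#'
#' @param x genes x cells expression matrix.
#' @param genes character vector of gene identifiers (one gene set).
#' @param set_name optional name used in error messages.
#' @return list with `ranks` (named, sums to `n_set * (n_set + 1) / 2`),
#'   `totals`, `n_set` (intersection size), `genes_used`, `genes_missing`.
#' @export
rank_weights <- function(x, genes, set_name = NULL) {
  genes <- unique(genes)
  present <- genes[genes %in% rownames(x)]
  if (length(present) == 0) {
    stop("gene set ", if (!is.null(set_name)) paste0("'", set_name, "' "),
         "has no genes in the matrix", call. = FALSE)
  }
  totals <- Matrix::rowSums(x[present, , drop = FALSE])
  ranks <- rank(totals, ties.method = "average")
  list(ranks = ranks, totals = totals, n_set = length(present),
       genes_used = present, genes_missing = setdiff(genes, present))
}

#' Per-cell pathway score for one gene set
#'
#' Implements the two-step scoring: (1) each gene is normalized by the
#' median of its top-tau% cells (maximum fallback, [norm_factors()]);
#' (2) the score of cell `j` is the rank-weighted sum of its normalized
#' gene scores,
#' `P[j] = (1 / n^2) * sum_i rank_i * S[i, j]`
#' with `n` the number of set genes present in the matrix. The default
#' denominator `n^2` follows the method's published formula; with
#' `denominator = "weighted_mean"` the sum of the weights
#' (`n * (n + 1) / 2`) is used instead so the score is a true weighted
#' average. Both are per-pathway constants and do not affect any downstream
#' test, Z-score, or ranking.
#'
#' @param x genes x cells expression matrix on linear scale (TPM/CPM). A
#'   matrix still tagged `"log"` triggers a warning, not an error.
#' @param genes character vector of gene identifiers (one direction of
#'   regulation per set).
#' @param tau percentage of top cells for the normalization median.
#' @param denominator `"np2"` (published `n^2`) or `"weighted_mean"`.
#' @param set_name optional name for error messages.
#' @return numeric vector of per-cell scores, named by cell; attributes
#'   `n_set`, `genes_used`, `genes_missing`, `tau`.
#' @examples
#' x <- expression_matrix(rbind(A = c(1, 2, 3), B = c(0, 1, 6)),
#'                        unit = "CPM", cell_ids = paste0("c", 1:3))
#' score_pathway(x, c("A", "B"), tau = 5) # 1/12, 1/4, 3/4
#' @export
score_pathway <- function(x, genes, tau = 5,
                          denominator = c("np2", "weighted_mean"),
                          set_name = NULL) {
  denominator <- match.arg(denominator)
  warn_if_log(x)
  rw <- rank_weights(x, genes, set_name = set_name)
  sub <- x[rw$genes_used, , drop = FALSE]
  nf <- norm_factors(sub, tau = tau)
  s <- normalize_genes(sub, nf)
  num <- as.numeric(Matrix::crossprod(s, rw$ranks))
  denom <- if (denominator == "np2") rw$n_set^2 else rw$n_set * (rw$n_set + 1) / 2
  p <- num / denom
  names(p) <- colnames(x)
  attr(p, "n_set") <- rw$n_set
  attr(p, "genes_used") <- rw$genes_used
  attr(p, "genes_missing") <- rw$genes_missing
  attr(p, "tau") <- tau
  p
}

warn_if_log <- function(x) {
  if (identical(matrix_unit(x), "log")) {
    warning("matrix unit is 'log'; pathway scores assume linear TPM/CPM ",
            "values -- consider delog()", call. = FALSE)
  }
  invisible(x)
}

#' Score a whole gene-set collection
#'
#' Scores every set of a collection against the same matrix. Sets with no
#' gene present in the matrix are skipped with a warning and listed in the
#' result's metadata, never silently dropped.
#'
#' @inheritParams score_pathway
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @return pathways x cells numeric matrix with attribute `"meta"`: a
#'   data.frame of per-set `n_set`, `n_genes`, `coverage`, and `skipped`,
#'   plus attribute `"tau"`.
#' @export
score_collection <- function(x, sets, tau = 5,
                             denominator = c("np2", "weighted_mean")) {
  denominator <- match.arg(denominator)
  if (length(sets) == 0) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names", call. = FALSE)
  }
  warn_if_log(x)
  present <- rownames(x)
  n_in_matrix <- vapply(sets, function(g) sum(unique(g) %in% present), integer(1))
  skipped <- names(sets)[n_in_matrix == 0]
  if (length(skipped) == length(sets)) {
    stop("no gene set overlaps the matrix genes", call. = FALSE)
  }
  if (length(skipped) > 0) {
    warning("skipping ", length(skipped), " gene set(s) with no genes in the matrix: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  }
  scored <- names(sets)[n_in_matrix > 0]

  # One pass of normalization factors over the union of used genes, then a
  # cheap rank-weighted cross product per set.
  union_genes <- unique(unlist(sets[scored], use.names = FALSE))
  union_genes <- union_genes[union_genes %in% present]
  sub <- x[union_genes, , drop = FALSE]
  nf <- norm_factors(sub, tau = tau)
  s <- normalize_genes(sub, nf)
  totals <- Matrix::rowSums(sub)

  out <- matrix(0, nrow = length(scored), ncol = ncol(x),
                dimnames = list(scored, colnames(x)))
  for (nm in scored) {
    g <- unique(sets[[nm]])
    g <- g[g %in% union_genes]
    ranks <- rank(totals[g], ties.method = "average")
    n_set <- length(g)
    denom <- if (denominator == "np2") n_set^2 else n_set * (n_set + 1) / 2
    out[nm, ] <- as.numeric(Matrix::crossprod(s[g, , drop = FALSE], ranks)) / denom
  }
  meta <- data.frame(
    set = names(sets),
    n_genes = vapply(sets, function(g) length(unique(g)), integer(1)),
    n_set = n_in_matrix,
    coverage = n_in_matrix / vapply(sets, function(g) length(unique(g)), integer(1)),
    skipped = n_in_matrix == 0,
    row.names = NULL
  )
  attr(out, "meta") <- meta
  attr(out, "tau") <- tau
  out
}
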