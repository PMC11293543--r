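#' Convert a log-scale matrix back to linear scale
#'
#' Published matrices are often distributed as `log_b(x + pseudocount)`;
#' pathway scoring operates on linear TPM/CPM, so such matrices are
#' de-logged first: `value <- base^value - pseudocount`, clipped at zero.
#' The default `base = 2`, `pseudocount = 1` matches the dominant
#' `log2(x + 1)` convention; both are exposed because the convention of a
#' given source dataset may differ and is rarely stated.
#'
#' @param x expression matrix with unit `"log"`.
#' @param base log base used by the source (> 1).
#' @param pseudocount pseudocount added before the log (>= 0).
#' @param unit linear unit the matrix is declared to be in after de-logging.
#' @return expression matrix on linear scale with the declared unit.
#' @export
delog <- function(x, base = 2, pseudocount = 1, unit = c("TPM", "CPM")) {
  unit <- match.arg(unit)
  if (base <= 1) stop("log base must be > 1", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  u <- matrix_unit(x)
  if (!is.na(u) && u != "log") {
    stop("delog expects a matrix with unit 'log', got '", u, "'", call. = FALSE)
  }
  dn <- dimnames(x)
  if (methods::is(x, "sparseMatrix")) x <- as.matrix(x)
  out <- base^x - pseudocount
  if (any(out < 0)) {
    warning("clipping ", sum(out < 0), " negative value(s) to 0 after de-log",
            call. = FALSE)
    out[out < 0] <- 0
  }
  # log(0 + 1) = 0 maps back to exactly 0; keep zeros sparse-friendly
  dimnames(out) <- dn
  expression_matrix(out, unit = unit)
}

filter_report <- function(axis, n_in, n_out, threshold) {
  list(axis = axis, n_in = n_in, n_out = n_out, n_removed = n_in - n_out,
       threshold = threshold)
}

#' Remove cells expressing too few genes
#'
#' Cells expressing (with at least one read) fewer than `min_genes` genes
#' are removed; a cell with exactly `min_genes` expressed genes is kept.
#' Survivor order is preserved.
#'
#' @param x nonnegative expression matrix.
#' @param min_genes minimum number of genes with value > 0 per kept cell.
#' @return list with elements `matrix` (filtered) and `report`.
#' @export
filter_cells <- function(x, min_genes = 1000) {
  genes_per_cell <- Matrix::colSums(x > 0)
  keep <- genes_per_cell >= min_genes
  report <- filter_report("cells", ncol(x), sum(keep), min_genes)
  if (!any(keep)) {
    stop("all ", ncol(x), " cells removed by the min_genes = ", min_genes,
         " filter", call. = FALSE)
  }
  out <- x[, keep, drop = FALSE]
  matrix_unit(out) <- matrix_unit(x)
  list(matrix = out, report = report)
}

#' Remove genes expressed in too small a fraction of cells
#'
#' Genes expressed in less than `min_cell_fraction` of the cells are
#' removed; a gene at exactly the threshold fraction is kept. Applied after
#' [filter_cells()] so the fraction refers to the remaining cells.
#'
#' @param x nonnegative expression matrix.
#' @param min_cell_fraction minimum fraction of cells with value > 0.
#' @return list with elements `matrix` and `report`.
#' @export
filter_genes <- function(x, min_cell_fraction = 0.10) {
  if (min_cell_fraction < 0 || min_cell_fraction > 1) {
    stop("min_cell_fraction must be in [0, 1]", call. = FALSE)
  }
  if (ncol(x) == 0 || nrow(x) == 0) stop("empty matrix", call. = FALSE)
  frac <- Matrix::rowSums(x > 0) / ncol(x)
  keep <- frac >= min_cell_fraction
  report <- filter_report("genes", nrow(x), sum(keep), min_cell_fraction)
  if (!any(keep)) {
    stop("all genes removed by the min_cell_fraction = ", min_cell_fraction,
         " filter", call. = FALSE)
  }
  out <- x[keep, , drop = FALSE]
  matrix_unit(out) <- matrix_unit(x)
  list(matrix = out, report = report)
}

#' Counts-per-million normalization
#'
#' Divides every value by the total counts of its cell and multiplies by one
#' million, so each cell column sums to 1e6. Applied to raw counts after
#' filtering.
#'
#' @param x expression matrix of counts; every cell total must be positive.
#' @return CPM expression matrix.
#' @export
cpm_normalize <- function(x) {
  u <- matrix_unit(x)
  if (!is.na(u) && u != "counts") {
    stop("cpm_normalize expects counts, got unit '", u, "'", call. = FALSE)
  }
  totals <- Matrix::colSums(x)
  if (any(totals <= 0)) {
    bad <- colnames(x)[totals <= 0]
    stop("cell(s) with zero total counts: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (methods::is(x, "sparseMatrix")) {
    out <- methods::as(x, "generalMatrix") %*%
      Matrix::Diagonal(ncol(x), 1e6 / totals)
    out <- methods::as(out, "CsparseMatrix")
    dimnames(out) <- dimnames(x)
  } else {
    out <- sweep(x, 2, totals / 1e6, "/")
  }
  expression_matrix(out, unit = "CPM")
}

#' Full preprocessing pipeline
#'
#' Fixed order: de-log (only for `unit = "log"` input), cell filter, gene
#' filter, CPM normalization (only for counts). Each filter is applied
#' exactly once, cells before genes, so the gene-expression fractions refer
#' to the cells that survive the cell filter.
#'
#' @param x expression matrix in counts, TPM/CPM, or log scale.
#' @param min_genes cell filter threshold, see [filter_cells()].
#' @param min_cell_fraction gene filter threshold, see [filter_genes()].
#' @param delog_base,delog_pseudocount de-log parameters, see [delog()].
#' @param delog_unit linear unit assumed for de-logged input.
#' @return list with `matrix` (ready for scoring) and `reports` (cell and
#'   gene filter reports).
#' @export
preprocess_matrix <- function(x, min_genes = 1000, min_cell_fraction = 0.10,
                              delog_base = 2, delog_pseudocount = 1,
                              delog_unit = "TPM") {
  u <- matrix_unit(x)
  if (identical(u, "log")) {
    x <- delog(x, base = delog_base, pseudocount = delog_pseudocount,
               unit = delog_unit)
    u <- matrix_unit(x)
  }
  fc <- filter_cells(x, min_genes = min_genes)
  fg <- filter_genes(fc$matrix, min_cell_fraction = min_cell_fraction)
  m <- fg$matrix
  if (identical(u, "counts")) m <- cpm_normalize(m)
  list(matrix = m, reports = list(cells = fc$report, genes = fg$report))
}
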