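#' Construct a validated expression matrix
#'
#' The package represents expression data as a genes x cells matrix (dense
#' `matrix` or sparse [Matrix::dgCMatrix-class]) with unique rownames (gene
#' identifiers), unique colnames (cell identifiers), and a `"unit"` attribute
#' recording the scale of the values. All scoring functions expect this
#' orientation; transposed dense input must be fixed explicitly by the caller
#' (see `transpose` in [read_matrix()]) and is never guessed.
#'
#' @param values numeric genes x cells matrix, dense or sparse, nonnegative
#'   unless `unit = "log"`.
#' @param unit one of `"TPM"`, `"CPM"`, `"counts"`, `"log"`. `"log"` marks a
#'   matrix on an unknown log scale that must pass through [delog()] before
#'   scoring.
#' @param gene_ids,cell_ids optional identifier vectors; default to the
#'   dimnames of `values`, which must then be present.
#' @return the matrix with dimnames set and a `"unit"` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("c1", "c2"))), unit = "counts")
#' matrix_unit(m)
#' @export
expression_matrix <- function(values, unit = c("TPM", "CPM", "counts", "log"),
                              gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  unit <- match.arg(unit)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("expression matrix needs gene and cell identifiers", call. = FALSE)
  }
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene identifiers must be unique (collapse duplicates first)",
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("cell identifiers must be unique", call. = FALSE)
  if (unit != "log" && min_value(values) < 0) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  attr(values, "unit") <- unit
  values
}

#' Unit tag of an expression matrix
#' @param x an expression matrix.
#' @return the `"unit"` attribute, or `NA` if unset.
#' @export
matrix_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

`matrix_unit<-` <- function(x, value) {
  attr(x, "unit") <- value
  x
}

# Minimum entry without densifying sparse input; empty matrix -> 0.
min_value <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    v <- methods::as(x, "generalMatrix")@x
    if (length(v) == 0) 0 else min(min(v), 0)
  } else if (length(x) == 0) 0 else min(x)
}

# Nonzero values of one gene (row) of a genes x cells matrix, as a list over
# all rows. Avoids row-indexing a dgCMatrix gene by gene.
row_nonzeros <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    t <- methods::as(methods::as(x, "generalMatrix"), "TsparseMatrix")
    out <- split(t@x, factor(t@i + 1L, levels = seq_len(nrow(x))))
  } else {
    out <- lapply(seq_len(nrow(x)), function(i) {
      v <- x[i, ]
      v[v != 0]
    })
  }
  names(out) <- rownames(x)
  out
}
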