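#' Read an expression matrix from MTX triplet or dense text
#'
#' Accepts either a directory (or `matrix.mtx` file path) holding a 10x-style
#' MatrixMarket triplet -- `matrix.mtx` plus `genes.tsv`/`features.tsv` (one
#' or two tab-separated columns, the gene identifier in the first that is
#' used, see Details) and `barcodes.tsv` (one barcode per line) -- or a dense
#' TSV/CSV file whose header row carries cell identifiers and whose first
#' column carries gene identifiers.
#'
#' Duplicated gene identifiers are collapsed by summing their rows (counts
#' and CPM are additive), with a warning. Negative entries are rejected.
#' Matrices are oriented genes x cells; a transposed dense file must be
#' declared with `transpose = TRUE`, it is never guessed.
#'
#' @details For two-column feature files the second column (gene symbol, as
#'   in 10x output) is used as the identifier, matching the symbols found in
#'   GMT collections; one-column files are used as is.
#'
#' @param path directory of an MTX triplet, a `.mtx` file, or a dense
#'   `.tsv`/`.csv` file.
#' @param unit declared unit of the values: `"TPM"`, `"CPM"`, `"counts"`, or
#'   `"log"` for log-scale matrices that need [delog()].
#' @param transpose set `TRUE` when a dense file is cells x genes.
#' @return a genes x cells expression matrix (sparse for MTX input) with a
#'   `"unit"` attribute; see [expression_matrix()].
#' @export
read_matrix <- function(path, unit = c("TPM", "CPM", "counts", "log"),
                        transpose = FALSE) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path) || grepl("\\.mtx$", path)) {
    m <- read_mtx_triplet(path)
  } else {
    m <- read_dense_table(path)
    if (transpose) m <- t(m)
  }
  if (min_value(m) < 0) stop("matrix contains negative entries", call. = FALSE)
  m <- collapse_duplicate_genes(m)
  expression_matrix(m, unit = unit)
}

read_mtx_triplet <- function(path) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- file.path(dir, "matrix.mtx")
  } else {
    dir <- dirname(path)
    mtx <- path
  }
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir, call. = FALSE)
  genes_file <- Filter(file.exists,
                       file.path(dir, c("genes.tsv", "features.tsv")))[1]
  barcodes_file <- file.path(dir, "barcodes.tsv")
  if (is.na(genes_file)) stop("genes.tsv/features.tsv not found in ", dir, call. = FALSE)
  if (!file.exists(barcodes_file)) stop("barcodes.tsv not found in ", dir, call. = FALSE)

  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e), call. = FALSE))
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  genes <- utils::read.delim(genes_file, header = FALSE,
                             colClasses = "character")
  gene_ids <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  barcodes <- readLines(barcodes_file)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(gene_ids) != nrow(m)) {
    stop("gene file has ", length(gene_ids), " entries but matrix declares ",
         nrow(m), " rows", call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcode file has ", length(barcodes), " entries but matrix declares ",
         ncol(m), " columns", call. = FALSE)
  }
  dimnames(m) <- list(gene_ids, barcodes)
  m
}

read_dense_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = NULL, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dense matrix file needs a gene-id column and at least one cell column",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in dense matrix file ", path, call. = FALSE)
  rownames(m) <- ids
  m
}

collapse_duplicate_genes <- function(m) {
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  dup <- unique(ids[duplicated(ids)])
  warning("collapsing ", length(dup), " duplicated gene identifier(s) by summation: ",
          paste(utils::head(dup, 5), collapse = ", "),
          if (length(dup) > 5) ", ..." else "", call. = FALSE)
  keep <- unique(ids)
  f <- factor(ids, levels = keep)
  if (methods::is(m, "sparseMatrix")) {
    ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(ids), x = 1,
                                dims = c(length(keep), length(ids)))
    out <- ind %*% m
    rownames(out) <- keep
    colnames(out) <- colnames(m)
    methods::as(out, "CsparseMatrix")
  } else {
    rowsum(m, group = f)
  }
}

#' Write an expression matrix
#'
#' `format = "mtx"` writes a 10x-style triplet (`matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`) into the directory `path`; `"tsv"`/`"csv"` write a dense
#' table with gene ids in the first column and cell ids in the header.
#'
#' @param x expression matrix (see [expression_matrix()]).
#' @param path output directory (mtx) or file (tsv/csv).
#' @param format `"mtx"`, `"tsv"` or `"csv"`; default guesses from `path`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv"
      else if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "mtx"
  }
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "genes.tsv"))
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    write_numeric_table(as.matrix(x), path, sep = sep, id_col = "gene")
  }
  invisible(path)
}

# Full-precision numeric table writer: %.17g survives a read-back exactly.
write_numeric_table <- function(m, path, sep = "\t", id_col = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = sep), con)
  if (nrow(m) > 0) {
    body <- apply(m, 1, function(v) paste(sprintf("%.17g", v), collapse = sep))
    writeLines(paste(rownames(m), body, sep = sep), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols. Empty lines are skipped; duplicate genes
#' within a line are dropped keeping the first occurrence; a line with fewer
#' than three fields or a duplicated set name is an error.
#'
#' @param path GMT file.
#' @param uppercase fold gene symbols to upper case (for matching MSigDB
#'   human symbols against mixed-case identifiers); off by default.
#' @return named list of character vectors (one per set) with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  sets <- list()
  descs <- character()
  for (ln in idx) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", ln, " has fewer than 3 fields", call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name '", name, "' at line ", ln, call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (uppercase) genes <- toupper(genes)
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0) {
      stop("GMT line ", ln, " (set '", name, "') has no genes", call. = FALSE)
    }
    sets[[name]] <- genes
    descs[[name]] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  attr(sets, "source") <- path
  sets
}

#' Write and read pathway-score tables
#'
#' Scores are written as a TSV with pathway rows, cell columns, and full
#' float precision so that `read_scores(write_scores(x, p))` reproduces `x`
#' exactly. Non-finite scores are rejected before writing.
#'
#' @param scores pathways x cells numeric matrix.
#' @param path TSV file.
#' @return `path` (write) or the score matrix (read).
#' @export
write_scores <- function(scores, path) {
  scores <- as.matrix(scores)
  if (length(scores) > 0 && !all(is.finite(scores))) {
    stop("scores contain non-finite values", call. = FALSE)
  }
  write_numeric_table(scores, path, sep = "\t", id_col = "pathway")
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read/write a cell-group assignment table
#'
#' Two-column TSV, `cell_id<TAB>group`, no header.
#'
#' @param path TSV file.
#' @param groups named character vector: names are cell ids, values group
#'   labels.
#' @return named character vector (read) or `path` invisibly (write).
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2) stop("group table must have exactly 2 columns", call. = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

#' @rdname read_groups
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
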