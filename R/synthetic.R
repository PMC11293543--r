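#' Specification for a synthetic scRNA-seq count matrix
#'
#' Describes a sparse, dropout-heavy count matrix with known ground truth.
#' Counts are negative binomial with a common baseline mean and dispersion;
#' genes belonging to a planted pathway have their mean multiplied by that
#' pathway's fold change in the affected cell group; independent Bernoulli
#' dropout then zeroes each entry. Optional batch definitions add a
#' constant offset to the counts of a gene subset in a cell subset,
#' emulating patient-specific artifacts confined to non-pathway genes.
#'
#' Defaults describe the generator's standard conditions: 1000 genes, two
#' groups of 100 cells, NB mean 2 with dispersion (size) 1, dropout 0.7 --
#' sparsity comparable to droplet scRNA-seq data -- and no planted
#' pathways (add them via `pathways` or [planted_pathways()]).
#'
#' @param n_genes total number of genes.
#' @param group_sizes integer vector of cells per group (labels `"g1"`,
#'   `"g2"`, ... unless named); each >= 2.
#' @param nb_mean baseline negative-binomial mean per gene and cell.
#' @param nb_dispersion NB dispersion (`size` parameter; variance =
#'   `mu + mu^2 / size`).
#' @param dropout_rate probability in \[0, 1) that any entry is zeroed.
#' @param pathways list of planted pathway definitions: each a list with
#'   `genes` (integer indices into 1..n_genes), `group` (affected group
#'   label, or `NA` for a null pathway) and `fold_change` (> 0; > 1 up,
#'   < 1 down, 1 null). See [planted_pathways()].
#' @param batches optional list of batch definitions: each a list with
#'   `cells` (integer indices), `genes` (integer indices) and `offset`
#'   (nonnegative count added).
#' @param seed integer seed making the draw reproducible.
#' @return validated `sipsic_sim_spec` list.
#' @export
synthetic_spec <- function(n_genes = 1000, group_sizes = c(100, 100),
                           nb_mean = 2, nb_dispersion = 1, dropout_rate = 0.7,
                           pathways = list(), batches = NULL, seed = 1) {
  stopifnot(n_genes >= 1, nb_mean > 0, nb_dispersion > 0)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (any(group_sizes < 2)) stop("every group needs >= 2 cells", call. = FALSE)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("g", seq_along(group_sizes))
  }
  for (p in pathways) {
    if (is.null(p$genes) || is.null(p$fold_change)) {
      stop("each pathway needs 'genes' and 'fold_change'", call. = FALSE)
    }
    if (any(p$genes < 1) || any(p$genes > n_genes)) {
      stop("pathway gene indices out of range", call. = FALSE)
    }
    if (p$fold_change <= 0) stop("fold_change must be > 0", call. = FALSE)
    if (!is.null(p$group) && !is.na(p$group) &&
        !(p$group %in% names(group_sizes))) {
      stop("pathway group '", p$group, "' is not a group label", call. = FALSE)
    }
  }
  if (is.null(names(pathways)) && length(pathways) > 0) {
    names(pathways) <- sprintf("PW%02d", seq_along(pathways))
  }
  for (b in batches) {
    if (any(b$cells < 1) || any(b$cells > sum(group_sizes)) ||
        any(b$genes < 1) || any(b$genes > n_genes) || b$offset < 0) {
      stop("invalid batch definition", call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, group_sizes = group_sizes,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate, pathways = pathways,
                 batches = batches, seed = seed),
            class = "sipsic_sim_spec")
}

#' Build a standard grid of planted pathway definitions
#'
#' Carves `n_pathways` disjoint blocks of `genes_per` consecutive genes and
#' assigns the requested fold changes and affected groups; remaining
#' pathways are null (`fold_change = 1`). Convenience for recovery and
#' calibration experiments.
#'
#' @param n_pathways number of pathways (blocks must fit in `n_genes`).
#' @param genes_per genes per pathway.
#' @param n_genes total genes of the target spec.
#' @param affected named list mapping pathway index (as character) to a
#'   list with `group` and `fold_change`.
#' @return list of pathway definitions for [synthetic_spec()].
#' @export
planted_pathways <- function(n_pathways = 50, genes_per = 20, n_genes = 1000,
                             affected = list()) {
  if (n_pathways * genes_per > n_genes) {
    stop("pathway blocks do not fit in n_genes", call. = FALSE)
  }
  out <- lapply(seq_len(n_pathways), function(i) {
    genes <- ((i - 1) * genes_per + 1):(i * genes_per)
    aff <- affected[[as.character(i)]]
    if (is.null(aff)) list(genes = genes, group = NA, fold_change = 1)
    else list(genes = genes, group = aff$group, fold_change = aff$fold_change)
  })
  names(out) <- sprintf("PW%02d", seq_len(n_pathways))
  out
}

#' Generate a synthetic count matrix with ground truth
#'
#' Draws the matrix described by a [synthetic_spec()]: NB counts with
#' planted per-group fold changes on pathway genes, then independent
#' dropout, then batch offsets. Fully reproducible from the spec's seed.
#'
#' @param spec a `sipsic_sim_spec`.
#' @return list with
#'   `counts`: sparse genes x cells count matrix (unit `"counts"`, gene ids
#'   `gene0001...`, cell ids `cell0001...`);
#'   `truth`: data.frame per pathway (name, group, fold_change, direction);
#'   `groups`: named character vector cell id -> group;
#'   `batch`: named character vector cell id -> batch label (`"b0"` when a
#'   cell is in no batch subset);
#'   `gene_sets`: named list of gene-id vectors for the planted pathways,
#'   ready for [score_collection()].
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sipsic_sim_spec"))
  n_cells <- sum(spec$group_sizes)
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  group_of <- rep(names(spec$group_sizes), spec$group_sizes)

  with_seed(spec$seed, {
    mu <- matrix(spec$nb_mean, nrow = spec$n_genes, ncol = n_cells)
    for (nm in names(spec$pathways)) {
      p <- spec$pathways[[nm]]
      if (!is.null(p$group) && !is.na(p$group) && p$fold_change != 1) {
        mu[p$genes, group_of == p$group] <-
          mu[p$genes, group_of == p$group] * p$fold_change
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = spec$nb_dispersion),
                     nrow = spec$n_genes)
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(length(mu)) >= spec$dropout_rate,
                     nrow = spec$n_genes)
      counts <- counts * keep
    }
    batch_label <- rep("b0", n_cells)
    for (i in seq_along(spec$batches)) {
      b <- spec$batches[[i]]
      counts[b$genes, b$cells] <- counts[b$genes, b$cells] + b$offset
      batch_label[b$cells] <- paste0("b", i)
    }
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  })
  dimnames(counts) <- list(gene_ids, cell_ids)
  counts <- expression_matrix(counts, unit = "counts")

  truth <- data.frame(
    pathway = names(spec$pathways),
    group = vapply(spec$pathways, function(p)
      if (is.null(p$group) || is.na(p$group)) NA_character_ else p$group, character(1)),
    fold_change = vapply(spec$pathways, `[[`, numeric(1), "fold_change"),
    row.names = NULL
  )
  truth$direction <- ifelse(is.na(truth$group) | truth$fold_change == 1, "ns",
                            ifelse(truth$fold_change > 1, "up", "down"))
  gene_sets <- lapply(spec$pathways, function(p) gene_ids[p$genes])
  list(counts = counts,
       truth = truth,
       groups = stats::setNames(group_of, cell_ids),
       batch = stats::setNames(batch_label, cell_ids),
       gene_sets = gene_sets)
}

#' Standard recovery spec for validation experiments
#'
#' The reference synthetic scenario used by the package's validation
#' harness: the generator defaults (1000 genes, two groups of 100 cells,
#' NB mean 2, dispersion 1, dropout 0.7) with 50 disjoint 20-gene pathways
#' of which five are upregulated threefold in group `g1` and five in
#' group `g2`; the remaining 40 are null.
#'
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
standard_recovery_spec <- function(seed = 1) {
  affected <- c(
    lapply(1:5, function(i) list(group = "g1", fold_change = 3)),
    lapply(6:10, function(i) list(group = "g2", fold_change = 3))
  )
  names(affected) <- as.character(1:10)
  synthetic_spec(pathways = planted_pathways(affected = affected), seed = seed)
}

#' Power / type-I recovery experiment
#'
#' Runs the full pipeline -- generate, filter, CPM-normalize, score, test --
#' over independent replicates of a synthetic spec and summarizes how often
#' each planted pathway is called in its true direction (power) and how
#' often null pathways are called at all (type-I rate).
#'
#' The cell filter uses `min_genes = 100` by default: simulated matrices
#' have ~1000 genes, so the droplet-data default of 1000 expressed genes
#' per cell is not meaningful here.
#'
#' @param spec a [synthetic_spec()] with at least one pathway.
#' @param n_replicates independent replicates (replicate r uses seed
#'   `spec$seed + r - 1`).
#' @param tau normalization window percentage passed to scoring.
#' @param fdr_threshold call threshold, see [pairwise_analysis()].
#' @param min_genes,min_cell_fraction preprocessing thresholds.
#' @return list with `power` (named vector over planted pathways),
#'   `type1_rate` (overall null call rate), `per_pathway` data.frame, and
#'   `n_replicates`.
#' @export
recovery_experiment <- function(spec, n_replicates = 20, tau = 5,
                                fdr_threshold = 0.01, min_genes = 100,
                                min_cell_fraction = 0.10) {
  stopifnot(inherits(spec, "sipsic_sim_spec"), length(spec$pathways) > 0)
  truth <- NULL
  correct <- NULL
  null_calls <- NULL
  for (r in seq_len(n_replicates)) {
    rspec <- spec
    rspec$seed <- spec$seed + r - 1
    sim <- simulate_counts(rspec)
    prep <- preprocess_matrix(sim$counts, min_genes = min_genes,
                              min_cell_fraction = min_cell_fraction)
    scores <- suppressWarnings(
      score_collection(prep$matrix, sim$gene_sets, tau = tau))
    diff <- pairwise_analysis(scores, sim$groups, fdr_threshold = fdr_threshold)
    truth <- sim$truth
    calls <- diff$calls
    hit <- logical(nrow(truth)); fp <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      pw <- truth$pathway[i]
      sub <- calls[calls$pathway == pw, ]
      if (truth$direction[i] == "ns") {
        fp[i] <- any(sub$direction != "ns")
      } else {
        hit[i] <- any(sub$direction == truth$direction[i] &
                        sub$group == truth$group[i])
      }
    }
    correct <- rbind(correct, hit)
    null_calls <- rbind(null_calls, fp)
  }
  planted <- truth$direction != "ns"
  power <- colMeans(correct)[planted]
  names(power) <- truth$pathway[planted]
  type1 <- if (any(!planted)) mean(null_calls[, !planted]) else NA_real_
  per_pathway <- data.frame(
    pathway = truth$pathway,
    direction = truth$direction,
    group = truth$group,
    rate = ifelse(planted, colMeans(correct), colMeans(null_calls)),
    row.names = NULL
  )
  list(power = power, type1_rate = type1, per_pathway = per_pathway,
       n_replicates = n_replicates)
}
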