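#' Per-pathway Z-scores
#'
#' Standardizes each pathway row of a score matrix individually:
#' `(x - mean) / sd`, with the sample standard deviation (denominator
#' `n - 1`). Constant rows cannot be standardized; they become all-zero and
#' are flagged in the `"constant_rows"` attribute.
#'
#' @param scores pathways x cells numeric matrix of finite scores.
#' @return matrix of the same shape; attributes `row_means`, `row_sds`,
#'   `constant_rows`.
#' @export
zscore <- function(scores) {
  scores <- as.matrix(scores)
  if (length(scores) > 0 && !all(is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  mu <- rowMeans(scores)
  sd <- apply(scores, 1, stats::sd)
  constant <- sd == 0 | is.na(sd)
  sd_safe <- ifelse(constant, 1, sd)
  z <- (scores - mu) / sd_safe
  z[constant, ] <- 0
  attr(z, "row_means") <- mu
  attr(z, "row_sds") <- sd
  attr(z, "constant_rows") <- rownames(scores)[constant]
  z
}

#' Cell and pathway ordering for pathway-score heatmaps
#'
#' Reproduces the standard heatmap layout for differential pathways: cells
#' are grouped; within each group they are sorted in ascending order of
#' their mean Z-score over the pathways upregulated in that group; pathway
#' rows form one block per group (groups in sorted label order), each block
#' sorted by ascending max-FDR so the most significant pathway comes first.
#' A group with no upregulated pathway keeps its input cell order, with a
#' warning.
#'
#' @param z Z-score matrix from [zscore()].
#' @param calls `calls` data.frame of a [pairwise_analysis()] result (or the
#'   result itself), computed on the same pathways.
#' @param groups named character vector cell id -> group label.
#' @return list with `cell_order` and `pathway_order` (character vectors of
#'   ids), plus `blocks`, a data.frame mapping each ordered pathway to its
#'   group and max-FDR.
#' @export
heatmap_order <- function(z, calls, groups) {
  if (inherits(calls, "sipsic_diff")) calls <- calls$calls
  groups <- groups[names(groups) %in% colnames(z)]
  labels <- sort(unique(unname(groups)))
  up <- calls[calls$direction == "up" & calls$pathway %in% rownames(z), ]

  path_blocks <- list()
  cell_order <- character(0)
  for (g in labels) {
    gp <- up[up$group == g, ]
    gp <- gp[order(gp$max_fdr, gp$pathway), ]
    cells <- names(groups)[groups == g]
    if (nrow(gp) == 0) {
      warning("group '", g, "' has no upregulated pathways; keeping input cell order",
              call. = FALSE)
    } else {
      path_blocks[[g]] <- data.frame(pathway = gp$pathway, group = g,
                                     max_fdr = gp$max_fdr)
      mean_z <- colMeans(z[gp$pathway, cells, drop = FALSE])
      cells <- cells[order(mean_z, cells)]
    }
    cell_order <- c(cell_order, cells)
  }
  blocks <- if (length(path_blocks)) do.call(rbind, c(path_blocks, list(make.row.names = FALSE)))
            else data.frame(pathway = character(0), group = character(0),
                            max_fdr = numeric(0))
  list(cell_order = cell_order, pathway_order = blocks$pathway, blocks = blocks)
}

# Symmetric k-nearest-neighbour graph from Euclidean distances between the
# columns of a cells-in-rows coordinate matrix.
knn_graph <- function(coords, n_neighbors) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(n_neighbors + 1)] # drop self at rank 1
    cbind(i, nb)
  })
  el <- unique(t(apply(do.call(rbind, edges), 1, sort)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Cluster cells in pathway-score space
#'
#' Cells are represented by their vector of pathway scores, standardized
#' per pathway ([zscore()]); a symmetric k-nearest-neighbour graph is built
#' on Euclidean distances in that space and partitioned with the Louvain
#' modularity algorithm at the given resolution. Because clustering happens
#' in pathway space (tens of dimensions) rather than gene space, no PCA
#' step is applied first.
#'
#' @param scores pathways x cells score matrix.
#' @param n_neighbors neighbours per cell for the kNN graph.
#' @param resolution Louvain resolution parameter (default 0.5).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return named integer vector of cluster labels (contiguous from 0,
#'   decreasing cluster size), one per cell, with attribute `"params"`.
#' @export
cluster_cells <- function(scores, n_neighbors = 20, resolution = 0.5, seed = 0) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  if (n < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " cells, got ", n,
         call. = FALSE)
  }
  coords <- t(zscore(scores))
  g <- knn_graph(coords, n_neighbors)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  labels <- relabel_by_size(as.integer(memb))
  names(labels) <- colnames(scores)
  attr(labels, "params") <- list(n_neighbors = n_neighbors,
                                 resolution = resolution, seed = seed)
  labels
}

# Relabel cluster ids 0..K-1 by decreasing size (ties by first appearance).
relabel_by_size <- function(memb) {
  tab <- sort(table(memb), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab) - 1L, names(tab))
  unname(map[as.character(memb)])
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' 2-D embedding of cells in pathway-score space
#'
#' UMAP on the per-pathway Z-scores; single-threaded and seeded so that
#' coordinates are reproducible on one machine and library version.
#'
#' @param scores pathways x cells score matrix.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size (reduced automatically for
#'   very small inputs).
#' @return cells x 2 matrix of finite coordinates, rownames = cell ids.
#' @export
embed_cells <- function(scores, seed = 0, n_neighbors = 15) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3) stop("need at least 3 cells to embed", call. = FALSE)
  z <- zscore(scores)
  if (all(z == 0)) stop("all pathway scores are constant; nothing to embed",
                        call. = FALSE)
  coords <- t(z)
  nb <- min(n_neighbors, nrow(coords) - 1)
  emb <- with_seed(seed, uwot::umap(coords, n_neighbors = nb, n_threads = 1,
                                    n_sgd_threads = 0))
  rownames(emb) <- colnames(scores)
  colnames(emb) <- c("UMAP1", "UMAP2")
  if (!all(is.finite(emb))) stop("embedding produced non-finite coordinates",
                                 call. = FALSE)
  emb
}

#' Cluster vs label contingency and dominant-label fractions
#'
#' Cross-tabulates a clustering against any other cell labelling (patient,
#' functional group, metamodule, ...) and reports, per cluster, the
#' dominant label and its fraction -- the statistic behind statements like
#' "in five clusters more than 99% of the cells were of a single patient".
#'
#' @param clusters named vector of cluster labels (e.g. [cluster_cells()]).
#' @param labels named character vector cell id -> label.
#' @return list with `table` (cluster x label counts) and `dominant`
#'   (data.frame: cluster, size, dominant label, fraction).
#' @export
cluster_composition <- function(clusters, labels) {
  cells <- intersect(names(clusters), names(labels))
  if (length(cells) == 0) stop("no shared cell ids", call. = FALSE)
  tab <- table(cluster = as.character(clusters[cells]),
               label = as.character(labels[cells]))
  dom <- data.frame(
    cluster = rownames(tab),
    size = as.integer(rowSums(tab)),
    dominant_label = colnames(tab)[apply(tab, 1, which.max)],
    dominant_fraction = apply(tab, 1, max) / rowSums(tab),
    row.names = NULL
  )
  list(table = tab, dominant = dom)
}
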