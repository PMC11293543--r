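#' Configuration for an end-to-end pipeline run
#'
#' Collects every parameter that affects pipeline output; [run_pipeline()]
#' records all of them in a JSON run manifest so two runs with equal
#' manifests produce equal outputs.
#'
#' @param matrix path to the expression matrix (MTX triplet directory or
#'   dense TSV/CSV), or an in-memory expression matrix.
#' @param gmt path to a GMT file, or an in-memory gene-set list.
#' @param groups optional path to a 2-column group table, or named vector;
#'   required for the differential stage.
#' @param out_dir output directory for artifacts.
#' @param unit declared unit of the input matrix.
#' @param tau,denominator scoring parameters, see [score_pathway()].
#' @param fdr_threshold,var_equal differential parameters, see
#'   [pairwise_analysis()].
#' @param min_genes,min_cell_fraction,delog_base,delog_pseudocount
#'   preprocessing parameters, see [preprocess_matrix()].
#' @param cluster run pathway-space clustering; `n_neighbors`, `resolution`
#'   apply, see [cluster_cells()].
#' @param embed also write a 2-D UMAP embedding.
#' @param n_neighbors,resolution clustering parameters.
#' @param seed integer seed for the stochastic stages.
#' @return a `sipsic_config` list.
#' @export
run_config <- function(matrix, gmt, groups = NULL, out_dir = ".",
                       unit = c("counts", "TPM", "CPM", "log"),
                       tau = 5, denominator = c("np2", "weighted_mean"),
                       fdr_threshold = 0.01, var_equal = TRUE,
                       min_genes = 1000, min_cell_fraction = 0.10,
                       delog_base = 2, delog_pseudocount = 1,
                       cluster = FALSE, embed = FALSE,
                       n_neighbors = 20, resolution = 0.5, seed = 0) {
  unit <- match.arg(unit)
  denominator <- match.arg(denominator)
  check_tau(tau)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "sipsic_config")
}

config_manifest <- function(config) {
  m <- lapply(unclass(config), function(v) {
    if (is.character(v) || is.numeric(v) || is.logical(v)) v else class(v)[1]
  })
  m$package_version <- as.character(utils::packageVersion("sipsic"))
  m
}

load_config_matrix <- function(config) {
  if (is.character(config$matrix)) read_matrix(config$matrix, unit = config$unit)
  else config$matrix
}

load_config_sets <- function(config) {
  if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
}

load_config_groups <- function(config) {
  if (is.null(config$groups)) NULL
  else if (is.character(config$groups) && length(config$groups) == 1 &&
           is.null(names(config$groups))) read_groups(config$groups)
  else config$groups
}

#' Run the full pipeline: preprocess, score, test, cluster
#'
#' Executes the stages in fixed order -- de-log if declared, cell filter,
#' gene filter, CPM for counts, pathway scoring, pairwise differential
#' analysis (when groups are given), optional pathway-space clustering and
#' embedding -- and writes `scores.tsv`, `calls.tsv`, `pairs.tsv`,
#' `clusters.tsv`, `umap.tsv` and `manifest.json` into `out_dir`. The
#' manifest logs every configuration parameter, the filter reports, and
#' any skipped gene sets.
#'
#' @param config a [run_config()].
#' @return list with the in-memory results (`scores`, `diff`, `clusters`,
#'   `embedding`, `reports`, `manifest`) and `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sipsic_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  x <- load_config_matrix(config)
  sets <- load_config_sets(config)
  groups <- load_config_groups(config)

  prep <- preprocess_matrix(x, min_genes = config$min_genes,
                            min_cell_fraction = config$min_cell_fraction,
                            delog_base = config$delog_base,
                            delog_pseudocount = config$delog_pseudocount)
  scores <- score_collection(prep$matrix, sets, tau = config$tau,
                             denominator = config$denominator)
  paths <- list(scores = file.path(config$out_dir, "scores.tsv"))
  write_scores(scores, paths$scores)

  diff <- NULL
  if (!is.null(groups)) {
    diff <- pairwise_analysis(scores, groups,
                              fdr_threshold = config$fdr_threshold,
                              var_equal = config$var_equal)
    paths$calls <- file.path(config$out_dir, "calls.tsv")
    write_calls(diff, paths$calls)
    paths$pairs <- file.path(config$out_dir, "pairs.tsv")
    utils::write.table(diff$pairs, paths$pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  clusters <- NULL
  embedding <- NULL
  if (isTRUE(config$cluster)) {
    clusters <- cluster_cells(scores, n_neighbors = config$n_neighbors,
                              resolution = config$resolution,
                              seed = config$seed)
    paths$clusters <- file.path(config$out_dir, "clusters.tsv")
    utils::write.table(data.frame(cell_id = names(clusters),
                                  cluster = unname(clusters)),
                       paths$clusters, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (isTRUE(config$embed)) {
    embedding <- embed_cells(scores, seed = config$seed)
    paths$umap <- file.path(config$out_dir, "umap.tsv")
    write_numeric_table(embedding, paths$umap, id_col = "cell_id")
  }

  meta <- attr(scores, "meta")
  manifest <- c(config_manifest(config),
                list(filter_reports = prep$reports,
                     skipped_sets = meta$set[meta$skipped],
                     n_pathways_scored = sum(!meta$skipped)))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(scores = scores, diff = diff, clusters = clusters,
       embedding = embedding, reports = prep$reports, manifest = manifest,
       paths = paths)
}

#' Robustness sweep over the normalization parameter tau
#'
#' Re-scores and re-tests the same data at several values of the top-tau%
#' normalization window and reports, per pathway, whether the
#' direction-call pattern (direction per group) is identical across all
#' tau values -- the per-dataset agreement statistic used to assess
#' robustness to tau.
#'
#' @param x preprocessed expression matrix (linear scale).
#' @param sets gene-set collection.
#' @param groups named cell id -> group vector.
#' @param taus numeric vector of at least 2 tau percentages (default
#'   `c(2, 5, 10)`).
#' @param fdr_threshold,var_equal,denominator see [pairwise_analysis()] and
#'   [score_pathway()].
#' @return list with `agreement`: data.frame (pathway, agree, plus one
#'   call-pattern column per tau); `n_agree`; `fraction_agree`; `taus`.
#' @export
tau_sweep <- function(x, sets, groups, taus = c(2, 5, 10),
                      fdr_threshold = 0.01, var_equal = TRUE,
                      denominator = "np2") {
  if (length(taus) < 2) stop("need at least 2 tau values", call. = FALSE)
  patterns <- list()
  for (tau in taus) {
    scores <- suppressWarnings(
      score_collection(x, sets, tau = tau, denominator = denominator))
    diff <- pairwise_analysis(scores, groups, fdr_threshold = fdr_threshold,
                              var_equal = var_equal)
    calls <- diff$calls[order(diff$calls$pathway, diff$calls$group), ]
    patterns[[as.character(tau)]] <- stats::setNames(
      tapply(paste0(calls$group, ":", calls$direction), calls$pathway,
             paste, collapse = ","),
      sort(unique(calls$pathway)))
  }
  pathways <- names(patterns[[1]])
  tab <- data.frame(pathway = pathways, row.names = NULL)
  for (tau in names(patterns)) tab[[paste0("tau_", tau)]] <- unname(patterns[[tau]][pathways])
  tab$agree <- apply(tab[, -1, drop = FALSE], 1,
                     function(v) length(unique(v)) == 1)
  list(agreement = tab, n_agree = sum(tab$agree),
       fraction_agree = mean(tab$agree), taus = taus)
}
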