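#' Two-group t-test on pathway scores
#'
#' Unpaired two-sided Student's t-test (pooled variance by default; Welch
#' with `var_equal = FALSE`) comparing the scores of one pathway between two
#' cell groups, plus the difference of group medians used for direction
#' calls. When both groups have zero variance the test is degenerate: equal
#' means give `t = 0, p = 1` by convention; unequal means are an error.
#'
#' @param a,b numeric score vectors, each of length >= 2.
#' @param var_equal `TRUE` for the pooled-variance Student test, `FALSE`
#'   for Welch.
#' @return list with `t_stat`, `p_value`, `median_diff` (`median(a) -
#'   median(b)`), `n_a`, `n_b`.
#' @export
t_test_pathway <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 cells", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("scores must be finite", call. = FALSE)
  }
  md <- stats::median(a) - stats::median(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t_stat = 0, p_value = 1, median_diff = md,
                  n_a = length(a), n_b = length(b)))
    }
    stop("zero variance in both groups with unequal means: t-test undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value, median_diff = md,
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, in input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise differential pathway analysis with max-FDR calls
#'
#' For every pair of cell groups, every pathway is tested with
#' [t_test_pathway()] and the p-values of that pair are adjusted together
#' by Benjamini-Hochberg across pathways. A pathway is called *up* in a
#' focal group only if its median difference is positive against **every**
#' other group and the largest of its pairwise FDRs is below the threshold
#' (*down* symmetrically); otherwise the call is *ns*. The reported
#' `max_fdr` is always the largest FDR across the focal group's pairs.
#'
#' Groups with fewer than 2 scored cells are excluded with a warning; at
#' least two usable groups are required.
#'
#' @param scores pathways x cells score matrix (e.g. [score_collection()]).
#' @param groups named character vector mapping cell id to group label;
#'   labeled cells absent from `scores` and scored cells without a label
#'   are ignored.
#' @param fdr_threshold significance threshold on the max FDR (default 0.01).
#' @param var_equal `TRUE` for Student (pooled) t-tests, `FALSE` for Welch.
#' @return list of class `sipsic_diff` with
#'   `calls`: data.frame (pathway, group, direction, max_fdr, n_pairs);
#'   `pairs`: data.frame of every pathway x pair test (t_stat, p_value,
#'   fdr, median_diff oriented group_a minus group_b, n_a, n_b);
#'   `fdr_threshold`.
#' @export
pairwise_analysis <- function(scores, groups, fdr_threshold = 0.01,
                              var_equal = TRUE) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0, 1)", call. = FALSE)
  }
  scores <- as.matrix(scores)
  groups <- groups[names(groups) %in% colnames(scores)]
  cells_by_group <- split(names(groups), unname(groups))
  sizes <- lengths(cells_by_group)
  if (any(sizes < 2)) {
    warning("excluding group(s) with < 2 cells: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    cells_by_group <- cells_by_group[sizes >= 2]
  }
  labels <- sort(names(cells_by_group))
  if (length(labels) < 2) {
    stop("need at least 2 groups with >= 2 cells each", call. = FALSE)
  }
  pathways <- rownames(scores)

  pair_rows <- list()
  for (i in seq_len(length(labels) - 1)) {
    for (j in seq((i + 1), length(labels))) {
      ga <- labels[i]; gb <- labels[j]
      sa <- scores[, cells_by_group[[ga]], drop = FALSE]
      sb <- scores[, cells_by_group[[gb]], drop = FALSE]
      res <- lapply(pathways, function(p) {
        t_test_pathway(sa[p, ], sb[p, ], var_equal = var_equal)
      })
      tab <- data.frame(
        pathway = pathways,
        group_a = ga, group_b = gb,
        t_stat = vapply(res, `[[`, numeric(1), "t_stat"),
        p_value = vapply(res, `[[`, numeric(1), "p_value"),
        median_diff = vapply(res, `[[`, numeric(1), "median_diff"),
        n_a = ncol(sa), n_b = ncol(sb)
      )
      # FDR family: all pathways within this one pairwise comparison
      tab$fdr <- bh_fdr(tab$p_value)
      pair_rows[[paste(ga, gb, sep = "|")]] <- tab
    }
  }
  pairs <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))

  calls <- do.call(rbind, lapply(labels, function(g) {
    others <- setdiff(labels, g)
    # orient every pair as focal minus other
    sub <- pairs[pairs$group_a == g | pairs$group_b == g, ]
    sign_flip <- ifelse(sub$group_a == g, 1, -1)
    sub$median_diff <- sub$median_diff * sign_flip
    agg_max_fdr <- tapply(sub$fdr, sub$pathway, max)
    all_pos <- tapply(sub$median_diff, sub$pathway, function(v) all(v > 0))
    all_neg <- tapply(sub$median_diff, sub$pathway, function(v) all(v < 0))
    pw <- pathways
    mf <- as.numeric(agg_max_fdr[pw])
    dir <- ifelse(mf < fdr_threshold & as.logical(all_pos[pw]), "up",
                  ifelse(mf < fdr_threshold & as.logical(all_neg[pw]), "down", "ns"))
    data.frame(pathway = pw, group = g, direction = dir, max_fdr = mf,
               n_pairs = length(others))
  }))
  rownames(calls) <- NULL
  structure(list(calls = calls, pairs = pairs, fdr_threshold = fdr_threshold),
            class = "sipsic_diff")
}

#' @export
print.sipsic_diff <- function(x, ...) {
  up <- sum(x$calls$direction == "up")
  dn <- sum(x$calls$direction == "down")
  cat("Pairwise differential pathway analysis\n")
  cat("  pathways:", length(unique(x$calls$pathway)),
      " groups:", length(unique(x$calls$group)), "\n")
  cat("  calls at FDR <", x$fdr_threshold, ":", up, "up,", dn, "down\n")
  invisible(x)
}

#' Write differential calls and per-pair statistics to TSV
#'
#' @param diff result of [pairwise_analysis()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_calls <- function(diff, path) {
  utils::write.table(diff$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
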