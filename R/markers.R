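#' Rank cluster marker genes by one-vs-rest Wilcoxon rank-sum test
#'
#' For every cluster, each gene is tested cluster-vs-all-other-cells with the
#' Wilcoxon rank-sum test (normal approximation with tie correction, no
#' continuity correction) on the log-normalized values, and genes are ranked
#' by two-sided p-value; ties are broken by decreasing |log fold-change|
#' (difference of group means on the log scale), then by gene ID.
#'
#' @param norm an `sc_norm` object from [normalize_counts()].
#' @param clusters per-cell cluster labels (length `ncol(norm$mat)`), or the
#'   name of a column of `norm$cells`; defaults to the `cell_type` column.
#' @param top_m number of top-ranked genes returned per cluster.
#' @return a named list (one element per cluster, in label order of first
#'   appearance) of data.frames with columns `gene`, `p_value`, `log_fc`.
#'   Clusters with fewer than 2 cells are skipped with a warning.
#' @export
rank_markers <- function(norm, clusters = NULL, top_m = 100L) {
  if (!inherits(norm, "sc_norm")) stopf("norm must be an sc_norm object")
  if (is.null(clusters)) clusters <- norm$cells$cluster %||% norm$cells$cell_type
  if (is.character(clusters) && length(clusters) == 1L &&
      clusters %in% names(norm$cells)) {
    clusters <- norm$cells[[clusters]]
  }
  if (length(clusters) != ncol(norm$mat)) {
    stopf("clusters must supply one label per cell")
  }
  top_m <- check_count(top_m, "top_m")
  labels <- unique(as.character(clusters))
  sizes <- table(factor(clusters, levels = labels))
  if (length(labels) < 2) stopf("need at least 2 clusters")
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    # skipped clusters get no marker list but their cells stay in "rest"
    warnf("skipping cluster(s) with < 2 cells: %s", paste(small, collapse = ", "))
    labels <- setdiff(labels, small)
  }
  if (length(labels) < 1) stopf("no cluster with >= 2 cells")

  X <- as.matrix(norm$mat)
  n <- ncol(X)
  G <- nrow(X)
  ranks <- matrix(0, G, n)
  tiesum <- numeric(G)  # sum of (t^3 - t) over tie groups, per gene
  for (g in seq_len(G)) {
    ranks[g, ] <- rank(X[g, ])
    tl <- rle(sort(X[g, ]))$lengths
    tiesum[g] <- sum(tl^3 - tl)
  }
  row_means <- rowMeans(X)

  out <- vector("list", length(labels))
  names(out) <- labels
  for (lab in labels) {
    in_cl <- clusters == lab
    n1 <- sum(in_cl)
    n2 <- n - n1
    r1 <- ranks[, in_cl, drop = FALSE] %*% rep(1, n1)
    U <- as.numeric(r1) - n1 * (n1 + 1) / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- ifelse(sigma2 <= 0, 1, 2 * pnorm(-abs(z)))
    lfc <- rowMeans(X[, in_cl, drop = FALSE]) -
      (row_means * n - rowMeans(X[, in_cl, drop = FALSE]) * n1) / n2
    ord <- order(p, -abs(lfc), rownames(X))
    top <- head(ord, top_m)
    out[[lab]] <- data.frame(gene = rownames(X)[top], p_value = p[top],
                             log_fc = lfc[top], row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  out
}

#' Principal-component gene loadings of a normalized matrix
#'
#' PCA is run on cells x genes (genes centered, not scaled); the returned
#' rotation matrix supplies the per-component gene loadings used for
#' feature-panel construction.
#'
#' @inheritParams rank_markers
#' @param n_components number of leading components to keep.
#' @return genes x components numeric matrix of loadings (rownames = gene
#'   IDs).
#' @export
pca_loadings <- function(norm, n_components = 20L) {
  if (!inherits(norm, "sc_norm")) stopf("norm must be an sc_norm object")
  n_components <- check_count(n_components, "n_components")
  n_components <- min(n_components, ncol(norm$mat) - 1L, nrow(norm$mat))
  pc <- prcomp(as.matrix(Matrix::t(norm$mat)), center = TRUE, scale. = FALSE,
               rank. = n_components)
  pc$rotation
}

#' Build the feature panel for discretization
#'
#' The panel is the deduplicated union of the top `top_m` marker genes of
#' every cluster and the `top_k` genes with largest absolute loading on each
#' of the first `n_components` embedding components. Order is deterministic:
#' marker blocks in cluster order (each by rank), then component blocks in
#' component order; the first occurrence of a duplicated gene wins.
#'
#' @param markers output of [rank_markers()] (a list of per-cluster ranked
#'   data.frames, or a list of character vectors already ranked).
#' @param loadings genes x components loading matrix ([pca_loadings()]), or
#'   `NULL` to build a marker-only panel.
#' @param top_m markers used per cluster (default 100).
#' @param top_k genes used per component (default 100).
#' @param n_components components used (default 20, capped at available).
#' @return a data.frame of class `feature_panel` with columns `gene` and
#'   `source` (provenance tag, e.g. `"cluster:typeA"` or `"component:3"`).
#' @export
build_panel <- function(markers, loadings = NULL, top_m = 100L, top_k = 100L,
                        n_components = 20L) {
  blocks <- list()
  for (lab in names(markers)) {
    m <- markers[[lab]]
    genes <- if (is.data.frame(m)) m$gene else as.character(m)
    genes <- head(genes, top_m)
    blocks[[length(blocks) + 1L]] <-
      data.frame(gene = genes, source = paste0("cluster:", lab),
                 stringsAsFactors = FALSE)
  }
  if (!is.null(loadings)) {
    n_components <- min(check_count(n_components, "n_components"),
                        ncol(loadings))
    for (k in seq_len(n_components)) {
      ord <- order(-abs(loadings[, k]), rownames(loadings))
      genes <- rownames(loadings)[head(ord, top_k)]
      blocks[[length(blocks) + 1L]] <-
        data.frame(gene = genes, source = paste0("component:", k),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(blocks) == 0L) stopf("empty feature panel")
  panel <- do.call(rbind, blocks)
  panel <- panel[!duplicated(panel$gene), , drop = FALSE]
  if (nrow(panel) == 0L) stopf("empty feature panel")
  rownames(panel) <- NULL
  class(panel) <- c("feature_panel", "data.frame")
  panel
}
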