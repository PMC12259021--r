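#' Read gene sets from GMT or plain gene-list files
#'
#' GMT: one set per line, tab-separated `name  description  gene1 gene2 ...`.
#' Plain list: one gene ID per line; the file becomes a single set named
#' after the file.
#'
#' @param path file path (`.gmt` treated as GMT; anything else as a plain
#'   list).
#' @return named list of unique gene-ID character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("gene-set file not found: %s", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3L) stopf("malformed GMT line: '%s'", f[1])
      unique(f[-(1:2)])
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
    sets
  } else {
    ids <- readLines(path)
    ids <- unique(ids[nzchar(ids)])
    setNames(list(ids), tools::file_path_sans_ext(basename(path)))
  }
}

# Equal-frequency bin index (1..n_bins) of each value of v.
quantile_bins <- function(v, n_bins) {
  as.integer(cut(rank(v, ties.method = "first"),
                 breaks = n_bins, labels = FALSE))
}

#' Gene-set module score with expression-bin-matched control genes
#'
#' Per-cell activity of a gene set, corrected for expression level: genes
#' are partitioned into `n_expr_bins` equal-frequency bins of their mean
#' expression across cells; for every bin containing target genes,
#' `n_ctrl_per_bin` control genes are sampled (without replacement, never
#' from the target set) from that bin; the score of a cell is its mean over
#' the target genes minus its mean over all selected control genes.
#'
#' With `ctrl_mode = "per_gene"` the alternative reading is used: 100 (i.e.
#' `n_ctrl_per_bin`) controls are drawn from the matching bin for each
#' target gene separately, with replacement across target genes' draws
#' pooled into one background set.
#'
#' @param norm an `sc_norm` object.
#' @param gene_set character vector of target gene IDs (or a single-set
#'   element of [read_gene_sets()]).
#' @param n_expr_bins number of equal-frequency mean-expression bins
#'   (default 24).
#' @param n_ctrl_per_bin control genes sampled per bin (default 100); if a
#'   bin has fewer eligible genes, all of them are used with a warning.
#' @param seed integer seed making the control draw reproducible.
#' @param ctrl_mode `"per_bin"` (default) or `"per_gene"`.
#' @return object of class `module_score`: list with `scores` (named
#'   per-cell numeric), `controls` (per-bin selected control genes),
#'   `target_genes` (those present in the matrix), `target_bins`, `params`.
#' @export
module_score <- function(norm, gene_set, n_expr_bins = 24L,
                         n_ctrl_per_bin = 100L, seed = 1L,
                         ctrl_mode = c("per_bin", "per_gene")) {
  if (!inherits(norm, "sc_norm")) stopf("norm must be an sc_norm object")
  ctrl_mode <- match.arg(ctrl_mode)
  n_expr_bins <- check_count(n_expr_bins, "n_expr_bins", min = 2L)
  n_ctrl_per_bin <- check_count(n_ctrl_per_bin, "n_ctrl_per_bin")
  gene_set <- unique(as.character(gene_set))
  all_genes <- rownames(norm$mat)
  present <- intersect(gene_set, all_genes)
  if (length(present) == 0L) {
    stopf("no target gene present in matrix; missing: %s",
          paste(head(gene_set, 10), collapse = ", "))
  }
  gene_means <- Matrix::rowMeans(norm$mat)
  bin_of <- quantile_bins(gene_means, n_expr_bins)
  names(bin_of) <- all_genes
  target_bins <- bin_of[present]

  controls <- with_seed(seed, {
    if (ctrl_mode == "per_bin") {
      bins <- sort(unique(target_bins))
      ctl <- lapply(bins, function(b) {
        pool <- setdiff(all_genes[bin_of == b], present)
        if (length(pool) == 0L) {
          warnf("expression bin %d has no non-target genes; no controls from it", b)
          return(character(0))
        }
        if (length(pool) < n_ctrl_per_bin) {
          warnf("expression bin %d has only %d non-target genes (< %d); using all",
                b, length(pool), n_ctrl_per_bin)
          return(pool)
        }
        sample(pool, n_ctrl_per_bin)
      })
      names(ctl) <- paste0("bin", bins)
      ctl
    } else {
      ctl <- lapply(present, function(g) {
        pool <- setdiff(all_genes[bin_of == bin_of[g]], present)
        if (length(pool) <= n_ctrl_per_bin) pool else sample(pool, n_ctrl_per_bin)
      })
      names(ctl) <- present
      ctl
    }
  })
  ctrl_genes <- unique(unlist(controls, use.names = FALSE))
  if (length(ctrl_genes) == 0L) stopf("no control genes could be selected")
  target_mean <- Matrix::colMeans(norm$mat[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm$mat[ctrl_genes, , drop = FALSE])
  scores <- target_mean - ctrl_mean
  structure(list(scores = scores, controls = controls,
                 target_genes = present, target_bins = target_bins,
                 params = list(n_expr_bins = n_expr_bins,
                               n_ctrl_per_bin = n_ctrl_per_bin,
                               seed = seed, ctrl_mode = ctrl_mode)),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("<module_score> %d cells, %d target genes, %d control genes (%s)\n",
              length(x$scores), length(x$target_genes),
              length(unique(unlist(x$controls, use.names = FALSE))),
              x$params$ctrl_mode))
  cat(sprintf("  score: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Pearson correlation between two per-cell score vectors
#'
#' Pearson r with a 95% confidence interval from the Fisher z-transform and
#' a two-sided p-value from the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param scores_a,scores_b numeric vectors of equal length (n >= 3);
#'   `module_score` objects are accepted and their `$scores` used.
#' @return object of class `correlation_result`: list with `r`, `ci95`
#'   (length-2 numeric), `p`, `n`.
#' @export
geneset_correlation <- function(scores_a, scores_b) {
  if (inherits(scores_a, "module_score")) scores_a <- scores_a$scores
  if (inherits(scores_b, "module_score")) scores_b <- scores_b$scores
  if (length(scores_a) != length(scores_b)) stopf("score vectors differ in length")
  n <- length(scores_a)
  if (n < 3L) stopf("need n >= 3 observations")
  if (sd(scores_a) == 0 || sd(scores_b) == 0) {
    stopf("constant score vector: correlation undefined")
  }
  ct <- cor.test(scores_a, scores_b, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
                 p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, 95%% CI [%.4f, %.4f], p = %.3g, n = %d\n",
              x$r, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}

#' Correlation between cell groups on top variable genes
#'
#' Per group and gene, the mean normalized expression is the representative
#' value; the `top_n` genes with the greatest standard deviation of these
#' group means (sample SD; ties broken by gene ID) are kept, and Pearson
#' correlations between group mean vectors over the kept genes form the
#' matrix.
#'
#' @param norm an `sc_norm` object.
#' @param groups per-cell group labels (length `ncol(norm$mat)`), or the
#'   name of a column of `norm$cells`.
#' @param top_n genes kept (default 1000); when more than available, all
#'   genes are used with a warning.
#' @return symmetric groups x groups correlation matrix with unit diagonal;
#'   the kept genes are attached as attribute `genes`.
#' @export
group_correlation <- function(norm, groups, top_n = 1000L) {
  if (!inherits(norm, "sc_norm")) stopf("norm must be an sc_norm object")
  if (is.character(groups) && length(groups) == 1L &&
      groups %in% names(norm$cells)) {
    groups <- norm$cells[[groups]]
  }
  if (length(groups) != ncol(norm$mat)) stopf("one group label per cell required")
  top_n <- check_count(top_n, "top_n")
  labels <- unique(as.character(groups))
  if (length(labels) < 2L) stopf("need >= 2 groups")
  ind <- sapply(labels, function(l) as.numeric(groups == l))
  gm <- as.matrix(norm$mat %*% ind) %*% diag(1 / colSums(ind), length(labels))
  colnames(gm) <- labels
  sds <- apply(gm, 1, sd)
  if (top_n > nrow(gm)) {
    warnf("top_n = %d exceeds %d available genes; using all", top_n, nrow(gm))
    top_n <- nrow(gm)
  }
  keep <- head(order(-sds, rownames(gm)), top_n)
  cm <- cor(gm[keep, , drop = FALSE], method = "pearson")
  diag(cm) <- 1
  attr(cm, "genes") <- rownames(gm)[keep]
  cm
}
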