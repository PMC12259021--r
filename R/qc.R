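#' Quality-control thresholds for cells and genes
#'
#' The four exclusion criteria: a cell is dropped when its UMI total is more
#' than `umi_max` or fewer than `umi_min`, when it expresses more than
#' `genes_max` or fewer than `genes_min` genes, or when over
#' `mito_frac_max` of its UMIs come from mitochondrial genes; a gene is
#' dropped when expressed in fewer than `gene_min_cells` cells. All bounds
#' are exclusive: a value exactly at a limit is retained ("more than" /
#' "fewer than" / "over").
#'
#' @param umi_max,umi_min UMI-total limits (defaults 10000 / 500).
#' @param genes_max,genes_min detected-gene limits (defaults 5000 / 300);
#'   a gene counts as detected in a cell when its count is > 0.
#' @param mito_frac_max maximum mitochondrial UMI fraction (default 0.10).
#' @param gene_min_cells minimum number of cells a gene must be expressed in
#'   (default 10).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(umi_max = 10000L, umi_min = 500L,
                          genes_max = 5000L, genes_min = 300L,
                          mito_frac_max = 0.10, gene_min_cells = 10L) {
  if (umi_min >= umi_max) stopf("umi_min must be < umi_max")
  if (genes_min >= genes_max) stopf("genes_min must be < genes_max")
  if (mito_frac_max < 0 || mito_frac_max > 1) {
    stopf("mito_frac_max must be in [0, 1]")
  }
  gene_min_cells <- check_count(gene_min_cells, "gene_min_cells", min = 0L)
  structure(list(umi_max = umi_max, umi_min = umi_min, genes_max = genes_max,
                 genes_min = genes_min, mito_frac_max = mito_frac_max,
                 gene_min_cells = gene_min_cells),
            class = "qc_thresholds")
}

as_sc_counts <- function(x) {
  if (inherits(x, "sc_counts")) return(x)
  stopf("expected an 'sc_counts' object (see simulate_counts / read_count_matrix)")
}

#' Filter cells on UMI total, detected genes, and mitochondrial fraction
#'
#' Retains exactly the cells with `umi_min <= UMI <= umi_max`,
#' `genes_min <= detected genes <= genes_max` and mito fraction
#' `<= mito_frac_max` (all limits inclusive on the retain side). A cell may
#' fail several criteria at once; the report itemizes each.
#'
#' @param x an `sc_counts` object with mitochondrial flags in `x$genes$mito`.
#' @param thresholds a [qc_thresholds()].
#' @return a list with `data` (the filtered `sc_counts`) and `report`
#'   (class `qc_report`: per-criterion exclusion counts, retained counts,
#'   and a per-cell flag table listing failing criteria).
#' @export
filter_cells <- function(x, thresholds = qc_thresholds()) {
  x <- as_sc_counts(x)
  t <- thresholds
  if (is.null(x$genes$mito) || all(is.na(x$genes$mito))) {
    stopf("no mitochondrial flags on genes; mito fraction is undefined")
  }
  umi <- Matrix::colSums(x$counts)
  ngene <- Matrix::colSums(x$counts > 0)
  mito_frac <- Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE]) /
    pmax(umi, 1)
  fail_umi <- umi > t$umi_max | umi < t$umi_min
  fail_genes <- ngene > t$genes_max | ngene < t$genes_min
  fail_mito <- mito_frac > t$mito_frac_max
  keep <- !(fail_umi | fail_genes | fail_mito)
  if (!any(keep)) warnf("all %d cells excluded by QC", ncol(x$counts))

  flags <- data.frame(barcode = colnames(x$counts), umi = as.numeric(umi),
                      n_genes = as.numeric(ngene),
                      mito_frac = as.numeric(mito_frac),
                      fail_umi = fail_umi, fail_genes = fail_genes,
                      fail_mito = fail_mito, retained = keep,
                      row.names = NULL, stringsAsFactors = FALSE)
  report <- structure(list(
    n_input = ncol(x$counts),
    n_retained = sum(keep),
    excluded_by = c(umi = sum(fail_umi), genes = sum(fail_genes),
                    mito = sum(fail_mito)),
    n_excluded = sum(!keep),
    thresholds = t,
    flags = flags), class = "qc_report")
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$cells <- x$cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  list(data = out, report = report)
}

#' Remove genes expressed in fewer than a minimum number of cells
#'
#' @inheritParams filter_cells
#' @return the filtered `sc_counts`; gene order is preserved.
#' @export
filter_genes <- function(x, thresholds = qc_thresholds()) {
  x <- as_sc_counts(x)
  support <- Matrix::rowSums(x$counts > 0)
  keep <- support >= thresholds$gene_min_cells
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$genes <- x$genes[keep, , drop = FALSE]
  rownames(out$genes) <- NULL
  out
}

#' Library-size log normalization
#'
#' Each count is scaled to the cell's total and log-transformed:
#' `value = ln(1 + count * scale_factor / cell_total)`. Zeros stay exactly
#' zero, so sparsity is preserved.
#'
#' @inheritParams filter_cells
#' @param scale_factor positive scaling constant (default 10000).
#' @return an object of class `sc_norm`: list with `mat` (sparse genes x
#'   cells log-normalized values), `genes`, `cells`, `scale_factor`.
#' @export
normalize_counts <- function(x, scale_factor = 10000) {
  x <- as_sc_counts(x)
  if (scale_factor <= 0) stopf("scale_factor must be > 0")
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stopf("%d cell(s) have zero total counts; run filter_cells first",
          sum(totals == 0))
  }
  mat <- methods::as(methods::as(x$counts, "CsparseMatrix"), "dMatrix")
  mat@x <- log1p(mat@x * scale_factor / rep.int(totals, diff(mat@p)))
  dimnames(mat) <- dimnames(x$counts)
  structure(list(mat = mat, genes = x$genes, cells = x$cells,
                 scale_factor = scale_factor), class = "sc_norm")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d cells in, %d retained (%d excluded)\n",
              x$n_input, x$n_retained, x$n_excluded))
  cat(sprintf("  failed UMI bounds: %d | gene bounds: %d | mito fraction: %d\n",
              x$excluded_by["umi"], x$excluded_by["genes"],
              x$excluded_by["mito"]))
  invisible(x)
}

#' @export
print.sc_norm <- function(x, ...) {
  cat(sprintf("<sc_norm> %d genes x %d cells, ln(1 + c * %g / total)\n",
              nrow(x$mat), ncol(x$mat), x$scale_factor))
  invisible(x)
}
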