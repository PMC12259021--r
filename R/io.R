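#' Write a count matrix as a 10x-style Matrix Market fixture
#'
#' Produces `matrix.mtx` (genes x cells, coordinate format), `genes.tsv`
#' (`id`, `symbol`, `mito`), `barcodes.tsv` (`barcode`), and `cells.tsv`
#' (per-cell metadata). Files round-trip bit-exactly through
#' [read_count_matrix()].
#'
#' @param x an `sc_counts` object.
#' @param dir output directory (created if missing).
#' @param gzip write `.gz`-compressed text files.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(x, dir, gzip = FALSE) {
  x <- as_sc_counts(x)
  if (ncol(x$counts) == 0L) stopf("refusing to write a fixture with 0 cells")
  if (nrow(x$counts) == 0L) stopf("refusing to write a fixture with 0 genes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  paths <- file.path(dir, paste0(c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                                   "cells.tsv"), ext))
  names(paths) <- c("matrix", "genes", "barcodes", "cells")
  m <- methods::as(x$counts, "CsparseMatrix")
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(m, tmp)
    con_in <- file(tmp, "rb"); con_out <- gzfile(paths["matrix"], "wb")
    writeBin(readBin(con_in, "raw", file.size(tmp)), con_out)
    close(con_in); close(con_out); unlink(tmp)
  } else {
    Matrix::writeMM(m, paths["matrix"])
  }
  wt <- function(df, p, col.names) {
    if (gzip) {
      con <- gzfile(p, "w")
      on.exit(close(con))
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = col.names)
    } else {
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = col.names)
    }
  }
  wt(x$genes, paths["genes"], col.names = TRUE)
  wt(data.frame(barcode = colnames(x$counts)), paths["barcodes"],
     col.names = FALSE)
  wt(x$cells, paths["cells"], col.names = TRUE)
  invisible(paths)
}

read_tsv_maybe_gz <- function(path, header) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  read.delim(con, header = header, sep = "\t", stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

find_input <- function(dir, base) {
  for (p in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a 10x-style Matrix Market triplet (plus optional cell metadata)
#'
#' Expects `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and optionally
#' `cells.tsv` in `dir` (each possibly `.gz`). Mitochondrial flags come
#' from a `mito` column of the gene table when present, otherwise from a
#' `"mt-"`/`"MT-"` symbol prefix. Cell metadata is joined to barcodes by
#' exact, case-sensitive match.
#'
#' @param dir directory containing the triplet.
#' @return an `sc_counts` object.
#' @export
read_count_matrix <- function(dir) {
  if (!dir.exists(dir)) stopf("input directory not found: %s", dir)
  pm <- find_input(dir, "matrix.mtx")
  pg <- find_input(dir, "genes.tsv")
  pb <- find_input(dir, "barcodes.tsv")
  if (is.null(pm) || is.null(pg) || is.null(pb)) {
    stopf("missing matrix.mtx / genes.tsv / barcodes.tsv under %s", dir)
  }
  m <- if (grepl("\\.gz$", pm)) {
    con <- gzfile(pm)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    Matrix::readMM(con)
  } else Matrix::readMM(pm)
  m <- methods::as(m, "CsparseMatrix")

  g1 <- local({
    con <- if (grepl("\\.gz$", pg)) gzfile(pg, "r") else file(pg, "r")
    on.exit(close(con))
    readLines(con, n = 1L)
  })
  genes_have_header <- grepl("^id\\t", g1) || identical(g1, "id")
  genes <- read_tsv_maybe_gz(pg, header = genes_have_header)
  if (!genes_have_header) {
    names(genes) <- c("id", "symbol", "mito")[seq_len(ncol(genes))]
  }
  if (is.null(genes$symbol)) genes$symbol <- genes$id
  if (is.null(genes$mito)) {
    genes$mito <- grepl("^(mt-|MT-)", genes$symbol)
  } else {
    genes$mito <- as.logical(genes$mito)
  }
  barcodes <- read_tsv_maybe_gz(pb, header = FALSE)[[1]]

  if (nrow(m) != nrow(genes)) {
    stopf("%s declares %d rows but %s has %d genes", basename(pm), nrow(m),
          basename(pg), nrow(genes))
  }
  if (ncol(m) != length(barcodes)) {
    stopf("%s declares %d columns but %s has %d barcodes", basename(pm),
          ncol(m), basename(pb), length(barcodes))
  }
  rownames(m) <- genes$id
  colnames(m) <- barcodes

  pc <- find_input(dir, "cells.tsv")
  if (!is.null(pc)) {
    cells <- read_tsv_maybe_gz(pc, header = TRUE)
    if (is.null(cells$barcode)) stopf("cells.tsv lacks a 'barcode' column")
    miss <- setdiff(barcodes, cells$barcode)
    if (length(miss)) {
      stopf("%d barcode(s) missing from cells.tsv, e.g.: %s", length(miss),
            paste(head(miss, 10), collapse = ", "))
    }
    cells <- cells[match(barcodes, cells$barcode), , drop = FALSE]
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  }
  structure(list(counts = m, genes = genes, cells = cells),
            class = "sc_counts")
}

#' Pipeline configuration
#'
#' Bundles and validates every parameter of [run_pipeline()]. Validation
#' happens here, before any compute.
#'
#' @param input directory with the count fixture ([read_count_matrix()]).
#' @param out_dir output directory.
#' @param thresholds a [qc_thresholds()].
#' @param scale_factor normalization scale factor.
#' @param gene_filter_first apply the gene-support filter before the cell
#'   filter (default `FALSE`: cells first, so gene support reflects
#'   retained cells).
#' @param n_bins,n_cells,n_draws,seed heterogeneity parameters
#'   (see [stage_heterogeneity()]).
#' @param top_m,top_k,n_components feature-panel parameters
#'   (see [build_panel()]).
#' @param gene_sets optional path to a GMT / gene-list file, or a named list
#'   of gene-ID vectors, for module scoring.
#' @param n_expr_bins,n_ctrl_per_bin module-score parameters.
#' @param group_by cell-metadata column for [group_correlation()]
#'   (default `"stage"`).
#' @param top_n_group_genes top variable genes for group correlation.
#' @param log_level `"info"` or `"quiet"`.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            thresholds = qc_thresholds(),
                            scale_factor = 10000,
                            gene_filter_first = FALSE,
                            n_bins = 10L, n_cells = 100L, n_draws = 500L,
                            seed = 1L,
                            top_m = 100L, top_k = 100L, n_components = 20L,
                            gene_sets = NULL,
                            n_expr_bins = 24L, n_ctrl_per_bin = 100L,
                            group_by = "stage", top_n_group_genes = 1000L,
                            log_level = c("info", "quiet")) {
  if (!dir.exists(input)) stopf("input directory not found: %s", input)
  if (!inherits(thresholds, "qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, thresholds)
  }
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gene_sets(gene_sets)
  }
  structure(list(
    input = input, out_dir = out_dir, thresholds = thresholds,
    scale_factor = scale_factor, gene_filter_first = isTRUE(gene_filter_first),
    n_bins = check_count(n_bins, "n_bins", 2L),
    n_cells = check_count(n_cells, "n_cells", 2L),
    n_draws = check_count(n_draws, "n_draws"),
    seed = check_count(seed, "seed", 0L),
    top_m = check_count(top_m, "top_m"),
    top_k = check_count(top_k, "top_k"),
    n_components = check_count(n_components, "n_components"),
    gene_sets = gene_sets,
    n_expr_bins = check_count(n_expr_bins, "n_expr_bins", 2L),
    n_ctrl_per_bin = check_count(n_ctrl_per_bin, "n_ctrl_per_bin"),
    group_by = group_by,
    top_n_group_genes = check_count(top_n_group_genes, "top_n_group_genes"),
    log_level = match.arg(log_level)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file whose keys mirror
#'   the arguments of [pipeline_config()]; `thresholds` may be a nested map.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else v
  }
  x$thresholds <- unclass(x$thresholds)
  jsonlite::toJSON(sort_rec(unclass(x)), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canonical_json(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(format(df, digits = 15, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full heterogeneity pipeline on a count fixture
#'
#' Executes QC -> normalization -> marker ranking -> feature panel ->
#' discretization -> stage NMI -> stage comparisons -> module scores (if
#' gene sets configured) -> group correlation, writing each result as TSV
#' (with `#` header comments naming parameters) plus a JSON run manifest.
#' Identical config + seed produces byte-identical numeric tables. On a
#' stage error the outputs produced so far are moved under
#' `<out_dir>/partial/` and the error is re-raised naming the stage.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stopf("config must be a pipeline_config or a config file path")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, fmt, ...) {
    if (config$log_level == "info") {
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
  }
  timings <- list()
  current_stage <- "setup"
  run_stage <- function(name, expr) {
    current_stage <<- name
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  tryCatch({
    inputs <- list.files(config$input, full.names = TRUE)
    x <- run_stage("read", read_count_matrix(config$input))
    log("read", "%d genes x %d cells", nrow(x$counts), ncol(x$counts))

    qc <- run_stage("qc", {
      if (config$gene_filter_first) x <- filter_genes(x, config$thresholds)
      fc <- filter_cells(x, config$thresholds)
      if (!config$gene_filter_first) {
        fc$data <- filter_genes(fc$data, config$thresholds)
      }
      fc
    })
    log("qc", "%d/%d cells retained, %d genes retained",
        qc$report$n_retained, qc$report$n_input, nrow(qc$data$counts))
    write_tsv_commented(qc$report$flags, file.path(out, "qc_report.tsv"),
      c("per-cell QC flags; bounds are exclusive on the exclusion side",
        sprintf("umi [%d, %d], genes [%d, %d], mito <= %g, gene support >= %d",
                config$thresholds$umi_min, config$thresholds$umi_max,
                config$thresholds$genes_min, config$thresholds$genes_max,
                config$thresholds$mito_frac_max,
                config$thresholds$gene_min_cells)))
    jsonlite::write_json(
      list(n_input = qc$report$n_input, n_retained = qc$report$n_retained,
           excluded_by = as.list(qc$report$excluded_by),
           n_genes_retained = nrow(qc$data$counts)),
      file.path(out, "qc_summary.json"), auto_unbox = TRUE)

    norm <- run_stage("normalize",
                      normalize_counts(qc$data, config$scale_factor))
    cluster_col <- if (!is.null(norm$cells$cluster)) "cluster" else "cell_type"
    markers <- run_stage("markers",
                         rank_markers(norm, cluster_col, config$top_m))
    loadings <- run_stage("pca", pca_loadings(norm, config$n_components))
    panel <- run_stage("panel",
                       build_panel(markers, loadings, config$top_m,
                                   config$top_k, config$n_components))
    log("panel", "%d genes", nrow(panel))
    write_tsv_commented(panel, file.path(out, "panel.tsv"),
      sprintf("feature panel: top %d markers/cluster + top %d genes x %d components",
              config$top_m, config$top_k, config$n_components))

    disc <- run_stage("discretize",
                      discretize(norm, panel, config$n_bins))
    het <- run_stage("heterogeneity",
                     stage_heterogeneity(disc, norm$cells, config$n_cells,
                                         config$n_draws, config$seed))
    draws <- data.frame(
      stage = rep(names(het$medians), lengths(het$medians)),
      draw = unlist(lapply(het$medians, seq_along), use.names = FALSE),
      median_nmi = unlist(het$medians, use.names = FALSE))
    write_tsv_commented(draws, file.path(out, "stage_nmi_draws.tsv"),
      sprintf("draw-median pairwise NMI (nats-based, unitless, in [0,1]); n_cells = %d, n_draws = %d, n_bins = %d, seed = %d",
              config$n_cells, config$n_draws, config$n_bins, config$seed))
    comp <- run_stage("compare", compare_stages(het, "t"))
    write_tsv_commented(comp, file.path(out, "stage_comparisons.tsv"),
      c("two-tailed unpaired Student's t-test on draw-median NMI vectors",
        attr(comp, "caveat")))

    if (!is.null(config$gene_sets)) {
      scores <- run_stage("score", {
        lapply(config$gene_sets, function(gs) {
          module_score(norm, gs, config$n_expr_bins, config$n_ctrl_per_bin,
                       seed = config$seed)
        })
      })
      sc_tab <- data.frame(barcode = colnames(norm$mat))
      for (nm in names(scores)) sc_tab[[nm]] <- unname(scores[[nm]]$scores)
      write_tsv_commented(sc_tab, file.path(out, "module_scores.tsv"),
        sprintf("bin-matched module scores; %d expression bins, %d controls/bin, seed = %d",
                config$n_expr_bins, config$n_ctrl_per_bin, config$seed))
      if (length(scores) >= 2L) {
        nm <- names(scores)
        prs <- combn(length(nm), 2)
        cr <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
          r <- geneset_correlation(scores[[prs[1, k]]], scores[[prs[2, k]]])
          data.frame(set_a = nm[prs[1, k]], set_b = nm[prs[2, k]],
                     r = r$r, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
                     p = r$p, n = r$n)
        }))
        write_tsv_commented(cr, file.path(out, "geneset_correlations.tsv"),
          "Pearson r between module scores; Fisher-z 95% CI; t-based p, df = n - 2")
      }
    }

    gcor <- run_stage("group_correlation",
                      group_correlation(norm, config$group_by,
                                        config$top_n_group_genes))
    gdf <- data.frame(group = rownames(gcor), as.data.frame(gcor),
                      check.names = FALSE)
    write_tsv_commented(gdf, file.path(out, "group_correlations.tsv"),
      sprintf("Pearson correlation between '%s' group mean profiles over top %d variable genes",
              config$group_by, min(config$top_n_group_genes, nrow(norm$mat))))

    manifest <- list(
      tool = "stagehet", version = as.character(packageVersion("stagehet")),
      config_hash = config_hash(config),
      seed = config$seed,
      input_checksums = as.list(tools::md5sum(inputs)),
      stage_seconds = timings,
      n_cells_in = qc$report$n_input, n_cells_retained = qc$report$n_retained,
      n_genes_retained = nrow(qc$data$counts), panel_size = nrow(panel))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    log("done", "outputs in %s", out)
    invisible(out)
  }, error = function(e) {
    part <- file.path(out, "partial")
    dir.create(part, showWarnings = FALSE, recursive = TRUE)
    done <- setdiff(list.files(out, full.names = TRUE), part)
    done <- done[!dir.exists(done)]
    file.rename(done, file.path(part, basename(done)))
    stopf("pipeline failed at stage '%s': %s", current_stage,
          conditionMessage(e))
  })
}
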