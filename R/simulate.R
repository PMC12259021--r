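#' Simulation configuration for a multi-stage single-cell count experiment
#'
#' Defines a synthetic multi-sample, multi-stage single-cell RNA-seq
#' experiment: negative binomial counts whose per-cell log-means combine a
#' per-gene baseline, a cell-type effect, a stage-specific per-cell jitter
#' (the heterogeneity knob), and optional injected gene programs, scaled to a
#' Gamma-distributed library size.
#'
#' @param n_genes total number of genes, including mitochondrial genes.
#' @param n_mito_genes number of mitochondrial genes; simulated as a flagged
#'   contiguous block at the top of the matrix with symbols prefixed "mt-".
#' @param stages ordered character vector of unique stage names. The default
#'   mirrors a premalignant lung progression series.
#' @param cells_per_stage cells simulated per stage (single value, >= 2).
#' @param n_cell_types number of discrete cell types.
#' @param base_expression optional positive numeric vector of per-gene mean
#'   weights (length `n_genes`). When `NULL`, weights are drawn log-normally
#'   with parameters `base_meanlog`, `base_sdlog`.
#' @param base_meanlog,base_sdlog log-normal location/scale used to draw
#'   `base_expression` when it is not supplied.
#' @param nb_dispersion negative binomial overdispersion phi (> 0); counts
#'   have variance mu + phi * mu^2, i.e. CV^2 = 1/mu + phi.
#' @param stage_noise_sd non-negative per-stage standard deviation of the
#'   iid Normal log-mean jitter applied independently per cell and gene.
#'   Recycled to `length(stages)`. This is the transcriptional-heterogeneity
#'   knob: larger values make cells of that stage less alike.
#' @param library_size_mean,library_size_shape mean and shape of the Gamma
#'   distribution of per-cell library sizes (total UMIs).
#' @param cell_type_effect_frac fraction of genes receiving a cell-type
#'   specific log-mean shift (distinct random subset per type).
#' @param cell_type_effect_mean,cell_type_effect_sd Normal parameters of that
#'   shift, in natural-log units.
#' @param cell_type_props optional matrix (`length(stages)` x `n_cell_types`)
#'   of per-stage cell-type mixing proportions; default uniform.
#' @param mito_frac_target expected fraction of a cell's UMIs coming from the
#'   mitochondrial block (baseline cells); mito gene weights are rescaled to
#'   hit it, so QC fixtures can be placed on either side of the 10% rule.
#' @param seed integer seed; the single source of randomness for the run.
#'   Per-stage sub-streams are derived deterministically from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [program_spec()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_mito_genes = 50L,
                       stages = c("normal", "AAH", "adenoma", "AIS"),
                       cells_per_stage = 600L,
                       n_cell_types = 3L,
                       base_expression = NULL,
                       base_meanlog = 0,
                       base_sdlog = 2,
                       nb_dispersion = 0.4,
                       stage_noise_sd = c(0.2, 0.6, 1.0, 1.4),
                       library_size_mean = 5000,
                       library_size_shape = 10,
                       cell_type_effect_frac = 0.05,
                       cell_type_effect_mean = 1.0,
                       cell_type_effect_sd = 0.25,
                       cell_type_props = NULL,
                       mito_frac_target = 0.05,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_mito_genes <- check_count(n_mito_genes, "n_mito_genes", min = 0L)
  if (n_mito_genes >= n_genes) stopf("n_mito_genes must be < n_genes")
  stages <- as.character(stages)
  if (length(stages) == 0L || anyDuplicated(stages) || any(is.na(stages))) {
    stopf("'stages' must be a non-empty vector of unique stage names")
  }
  cells_per_stage <- check_count(cells_per_stage, "cells_per_stage", min = 2L)
  n_cell_types <- check_count(n_cell_types, "n_cell_types")
  if (!is.null(base_expression)) {
    if (length(base_expression) != n_genes || any(base_expression <= 0)) {
      stopf("base_expression must be %d strictly positive values", n_genes)
    }
  }
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  stage_noise_sd <- rep_len(as.numeric(stage_noise_sd), length(stages))
  if (any(stage_noise_sd < 0)) stopf("stage_noise_sd must be >= 0")
  if (library_size_mean <= 0 || library_size_shape <= 0) {
    stopf("library size parameters must be > 0")
  }
  if (!is.null(cell_type_props)) {
    cell_type_props <- as.matrix(cell_type_props)
    if (!all(dim(cell_type_props) == c(length(stages), n_cell_types)) ||
        any(cell_type_props < 0)) {
      stopf("cell_type_props must be a non-negative %d x %d matrix",
            length(stages), n_cell_types)
    }
  }
  if (mito_frac_target <= 0 || mito_frac_target >= 1) {
    stopf("mito_frac_target must be in (0, 1)")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_genes = n_genes, n_mito_genes = n_mito_genes, stages = stages,
    cells_per_stage = cells_per_stage, n_cell_types = n_cell_types,
    base_expression = base_expression, base_meanlog = base_meanlog,
    base_sdlog = base_sdlog, nb_dispersion = nb_dispersion,
    stage_noise_sd = stage_noise_sd, library_size_mean = library_size_mean,
    library_size_shape = library_size_shape,
    cell_type_effect_frac = cell_type_effect_frac,
    cell_type_effect_mean = cell_type_effect_mean,
    cell_type_effect_sd = cell_type_effect_sd,
    cell_type_props = cell_type_props,
    mito_frac_target = mito_frac_target, seed = seed
  ), class = "sim_config")
}

#' Specify a gene program to inject into a simulated subpopulation
#'
#' A program is a gene set whose log2 expression is shifted by
#' `effect_log2fc` in cells of one cell type within selected stages —
#' e.g. a stage-restricted macrophage activity program.
#'
#' @param gene_ids character vector of simulated gene IDs (must exist in the
#'   simulated universe).
#' @param target_cell_type cell-type label (`"type1"`, `"type2"`, ...).
#' @param target_stages subset of configured stage names.
#' @param effect_log2fc log2 fold-change applied to program genes in targeted
#'   cells.
#' @return an object of class `program_spec`.
#' @export
program_spec <- function(gene_ids, target_cell_type, target_stages,
                         effect_log2fc) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stopf("program gene_ids must be non-empty")
  if (length(target_cell_type) != 1L) stopf("one target_cell_type required")
  if (!is.finite(effect_log2fc)) stopf("effect_log2fc must be finite")
  structure(list(gene_ids = gene_ids,
                 target_cell_type = as.character(target_cell_type),
                 target_stages = as.character(target_stages),
                 effect_log2fc = as.numeric(effect_log2fc)),
            class = "program_spec")
}

sim_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate a multi-stage single-cell count matrix with ground truth
#'
#' Counts are negative binomial draws. For cell c of stage s and gene g the
#' log relative expression is
#' `log(base[g]) + type_effect[g, type(c)] + N(0, stage_noise_sd[s]) +
#' log(2) * effect_log2fc` (the last term for injected program genes in
#' targeted cells); weights are renormalized per cell and scaled to a
#' Gamma-drawn library size to give the NB mean. Identical
#' `(config, programs)` input yields bit-identical output; each stage uses a
#' deterministic sub-seed so adding a stage leaves other stages unchanged.
#'
#' @param config a [sim_config()].
#' @param programs list of [program_spec()] objects (possibly empty).
#' @return an object of class `sc_sim` (inherits `sc_counts`): a list with
#'   `counts` (sparse genes x cells dgCMatrix), `genes` (data.frame with
#'   `id`, `symbol`, `mito`), `cells` (data.frame with `barcode`, `stage`,
#'   `sample`, `cell_type`), and `truth` (per-cell true labels, per-gene
#'   program membership, per-cell x program applied-effect matrix).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, cells_per_stage = 50,
#'                                   stages = c("normal", "AIS"), seed = 7))
#' dim(sim$counts)
#' table(sim$cells$stage)
#' @export
simulate_counts <- function(config, programs = list()) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  if (inherits(programs, "program_spec")) programs <- list(programs)
  gene_ids <- sim_gene_ids(config$n_genes)
  mito <- seq_len(config$n_genes) <= config$n_mito_genes
  symbols <- ifelse(mito, paste0("mt-", gene_ids), gene_ids)
  type_labels <- paste0("type", seq_len(config$n_cell_types))

  for (p in programs) {
    if (!inherits(p, "program_spec")) stopf("programs must be program_spec objects")
    bad <- setdiff(p$gene_ids, gene_ids)
    if (length(bad)) stopf("program gene(s) not in simulated universe: %s",
                           paste(head(bad, 5), collapse = ", "))
    if (!p$target_cell_type %in% type_labels) {
      stopf("unknown target_cell_type '%s'", p$target_cell_type)
    }
    bad <- setdiff(p$target_stages, config$stages)
    if (length(bad)) stopf("unknown target stage(s): %s",
                           paste(bad, collapse = ", "))
  }

  # gene-level parameters: one draw from the config seed
  gene_par <- with_seed(config$seed, {
    base <- config$base_expression %||%
      rlnorm(config$n_genes, config$base_meanlog, config$base_sdlog)
    # rescale the mito block so its expected UMI share hits the target
    if (config$n_mito_genes > 0L) {
      tot <- sum(base)
      f <- config$mito_frac_target
      base[mito] <- base[mito] * f * sum(base[!mito]) / ((1 - f) * sum(base[mito]))
    }
    eff <- matrix(0, config$n_genes, config$n_cell_types)
    n_eff <- max(1L, round(config$cell_type_effect_frac * config$n_genes))
    for (t in seq_len(config$n_cell_types)) {
      idx <- sample.int(config$n_genes, n_eff)
      eff[idx, t] <- rnorm(n_eff, config$cell_type_effect_mean,
                           config$cell_type_effect_sd)
    }
    list(base = base, type_effect = eff)
  })

  props <- config$cell_type_props
  n_stage <- length(config$stages)
  counts_list <- vector("list", n_stage)
  cells_list <- vector("list", n_stage)
  applied_list <- vector("list", n_stage)
  size <- 1 / config$nb_dispersion
  shape <- config$library_size_shape

  for (s in seq_len(n_stage)) {
    stage <- config$stages[s]
    nc <- config$cells_per_stage
    pr <- if (is.null(props)) rep(1, config$n_cell_types) else props[s, ]
    res <- with_seed(config$seed + 104729L * s, {
      ctype <- sample(type_labels, nc, replace = TRUE, prob = pr)
      logmean <- log(gene_par$base) +
        gene_par$type_effect[, match(ctype, type_labels), drop = FALSE]
      if (config$stage_noise_sd[s] > 0) {
        logmean <- logmean +
          matrix(rnorm(config$n_genes * nc, 0, config$stage_noise_sd[s]),
                 config$n_genes, nc)
      }
      applied <- matrix(FALSE, nc, length(programs))
      for (k in seq_along(programs)) {
        p <- programs[[k]]
        if (!stage %in% p$target_stages) next
        tc <- which(ctype == p$target_cell_type)
        if (length(tc)) {
          gi <- match(p$gene_ids, gene_ids)
          logmean[gi, tc] <- logmean[gi, tc] + log(2) * p$effect_log2fc
          applied[tc, k] <- TRUE
        }
      }
      w <- exp(logmean)
      lib <- rgamma(nc, shape = shape, rate = shape / config$library_size_mean)
      mu <- sweep(w, 2, lib / colSums(w), `*`)
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = size),
                    config$n_genes, nc)
      list(counts = cnt, ctype = ctype, applied = applied)
    })
    counts_list[[s]] <- res$counts
    applied_list[[s]] <- res$applied
    cells_list[[s]] <- data.frame(
      barcode = sprintf("%s_c%04d", stage, seq_len(nc)),
      stage = stage, sample = paste0(stage, "_s1"),
      cell_type = res$ctype, stringsAsFactors = FALSE)
  }

  counts <- methods::as(Matrix::Matrix(do.call(cbind, counts_list),
                                       sparse = TRUE), "CsparseMatrix")
  cells <- do.call(rbind, cells_list)
  rownames(counts) <- gene_ids
  colnames(counts) <- cells$barcode
  genes <- data.frame(id = gene_ids, symbol = symbols, mito = mito,
                      stringsAsFactors = FALSE)
  applied <- do.call(rbind, applied_list)
  rownames(applied) <- cells$barcode
  program_genes <- lapply(programs, `[[`, "gene_ids")
  truth <- list(
    cell_type = setNames(cells$cell_type, cells$barcode),
    stage = setNames(cells$stage, cells$barcode),
    program_genes = program_genes,
    applied = applied,
    effect_log2fc = vapply(programs, `[[`, numeric(1), "effect_log2fc"),
    expected_weight = gene_par$base)
  structure(list(counts = counts, genes = genes, cells = cells, truth = truth),
            class = c("sc_sim", "sc_counts"))
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<%s> %d genes x %d cells (%d mito genes)\n",
              class(x)[1], nrow(x$counts), ncol(x$counts), sum(x$genes$mito)))
  if (!is.null(x$cells$stage)) {
    tb <- table(x$cells$stage)
    cat("stages:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}
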