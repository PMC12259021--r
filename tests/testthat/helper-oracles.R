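# Independent scalar oracles and hand-built fixtures used across test files.
# The oracles deliberately avoid every code path of the package: mutual
# information by explicit enumeration of the joint count table, Pearson
# r / CI / p by the textbook formulas.

oracle_entropy <- function(x) {
  vals <- unique(x)
  p <- vapply(vals, function(a) mean(x == a), numeric(1))
  -sum(p * log(p))
}

oracle_mi <- function(x, y) {
  L <- length(x)
  I <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / L
      if (pxy > 0) {
        I <- I + pxy * log(pxy / ((sum(x == a) / L) * (sum(y == b) / L)))
      }
    }
  }
  I
}

oracle_nmi <- function(x, y) {
  Hx <- oracle_entropy(x)
  Hy <- oracle_entropy(y)
  if (Hx <= 0 || Hy <= 0) return(0)
  oracle_mi(x, y) / sqrt(Hx * Hy)
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) / ((n - 1) * sd(a) * sd(b))
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci = ci, p = 2 * pt(-abs(tstat), n - 2))
}

# Build an sc_counts object directly from a dense matrix.
make_counts <- function(m, mito = rep(FALSE, nrow(m)), cells = NULL) {
  gene_ids <- sprintf("g%04d", seq_len(nrow(m)))
  barcodes <- sprintf("bc%04d", seq_len(ncol(m)))
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  if (is.null(cells)) {
    cells <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  } else {
    cells$barcode <- barcodes
  }
  structure(list(counts = counts,
                 genes = data.frame(id = gene_ids, symbol = gene_ids,
                                    mito = mito, stringsAsFactors = FALSE),
                 cells = cells),
            class = "sc_counts")
}

# Hand-built six-cell QC fixture. Per cell: (UMI total, detected genes,
# mito UMIs). Mito counts sit on gene 1 (the only flagged gene); detected
# non-mito genes get count 1 each except the first, which absorbs the
# remainder so totals come out exactly.
#   cell 1: 400 UMIs (fails low-UMI), 350 genes, 5% mito
#   cell 2: 600 UMIs, 299 genes (fails low-gene), 5% mito
#   cell 3: 10001 UMIs (fails high-UMI), 400 genes, ~5% mito
#   cell 4: 2000 UMIs, 400 genes, 11% mito (fails mito)
#   cell 5: 6000 UMIs, 5001 genes (fails high-gene), 5% mito
#   cell 6: 2000 UMIs, 400 genes, 5% mito (retained)
make_qc_fixture <- function() {
  spec <- list(c(400, 350, 20), c(600, 299, 30), c(10001, 400, 500),
               c(2000, 400, 220), c(6000, 5001, 300), c(2000, 400, 100))
  n_genes <- 5100L
  m <- matrix(0, n_genes, 6L)
  for (j in seq_along(spec)) {
    u <- spec[[j]][1]; g <- spec[[j]][2]; mt <- spec[[j]][3]
    m[1, j] <- mt                      # mito gene counts as detected
    nonmito <- g - 1L                  # remaining detected genes
    m[1L + seq_len(nonmito), j] <- 1
    m[2, j] <- u - mt - (nonmito - 1L) # absorb remainder
  }
  stopifnot(colSums(m) == sapply(spec, `[`, 1),
            colSums(m > 0) == sapply(spec, `[`, 2))
  make_counts(m, mito = c(TRUE, rep(FALSE, n_genes - 1L)))
}

# Small simulated dataset shared by several files (kept deliberately small).
small_sim <- function(seed = 42, stages = c("lo", "hi"),
                      stage_noise_sd = c(0.2, 1.2), cells_per_stage = 120,
                      n_genes = 500, programs = list(), ...) {
  simulate_counts(sim_config(n_genes = n_genes, n_mito_genes = 20,
                             stages = stages, cells_per_stage = cells_per_stage,
                             stage_noise_sd = stage_noise_sd, seed = seed, ...),
                  programs)
}
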