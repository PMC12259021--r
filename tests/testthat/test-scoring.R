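make_norm <- function(m, ids = sprintf("g%04d", seq_len(nrow(m)))) {
  mat <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  rownames(mat) <- ids
  colnames(mat) <- sprintf("bc%04d", seq_len(ncol(m)))
  structure(list(mat = mat,
                 genes = data.frame(id = ids),
                 cells = data.frame(barcode = colnames(mat)),
                 scale_factor = 10000), class = "sc_norm")
}

test_that("module score is zero on a constant matrix and shifts with the targets", {
  norm <- make_norm(matrix(3, 60, 15))
  ms <- suppressWarnings(  # tiny bins: fewer controls than requested
    module_score(norm, sprintf("g%04d", 1:10), n_expr_bins = 4,
                 n_ctrl_per_bin = 10, seed = 1))
  expect_equal(unname(ms$scores), rep(0, 15), tolerance = 1e-12)
  expect_length(ms$target_genes, 10)
  # controls never include targets
  expect_length(intersect(unlist(ms$controls), ms$target_genes), 0)

  # shift equivariance: +c on all target rows raises every score by exactly
  # c. Targets are placed at the top of the mean-expression ranking so the
  # shift cannot re-bin any gene and the control draw stays identical.
  set.seed(2)
  m <- matrix(rexp(60 * 15), 60, 15)
  m[5:14, ] <- m[5:14, ] + 10
  norm2 <- make_norm(m)
  base <- suppressWarnings(
    module_score(norm2, sprintf("g%04d", 5:14), n_expr_bins = 4,
                 n_ctrl_per_bin = 8, seed = 3))
  m2 <- m
  m2[5:14, ] <- m2[5:14, ] + 1.5
  shifted <- suppressWarnings(
    module_score(make_norm(m2), sprintf("g%04d", 5:14),
                 n_expr_bins = 4, n_ctrl_per_bin = 8, seed = 3))
  expect_identical(shifted$controls, base$controls)
  expect_equal(unname(shifted$scores - base$scores), rep(1.5, 15),
               tolerance = 1e-10)
})

test_that("module score is deterministic under a fixed seed and errors on absent sets", {
  sim <- small_sim(seed = 3)
  norm <- normalize_counts(sim)
  gs <- sprintf("gene%05d", 101:140)
  a <- module_score(norm, gs, n_ctrl_per_bin = 5, seed = 11)
  b <- module_score(norm, gs, n_ctrl_per_bin = 5, seed = 11)
  expect_identical(a$scores, b$scores)
  expect_identical(a$controls, b$controls)
  c2 <- module_score(norm, gs, n_ctrl_per_bin = 5, seed = 12)
  expect_false(identical(a$controls, c2$controls))
  expect_error(module_score(norm, c("nope1", "nope2")), "nope1")
  # every target gene maps to exactly one expression bin
  expect_length(a$target_bins, length(intersect(gs, rownames(norm$mat))))
})

test_that("cells carrying an injected program outscore background cells", {
  genes <- sprintf("gene%05d", 301:350)
  prog <- program_spec(genes, "type1", "hi", effect_log2fc = 2)
  sim <- small_sim(seed = 6, programs = list(prog), n_cell_types = 2,
                   n_genes = 1000)
  norm <- normalize_counts(sim)
  ms <- module_score(norm, genes, seed = 1)
  targeted <- sim$truth$applied[, 1]
  tt <- t.test(ms$scores[targeted], ms$scores[!targeted])
  expect_gt(mean(ms$scores[targeted]), mean(ms$scores[!targeted]))
  expect_lt(tt$p.value, 0.01)
})

test_that("gene-set correlation matches the textbook Pearson oracle", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 6)
  r <- geneset_correlation(a, b)
  o <- oracle_pearson(a, b)
  expect_equal(r$r, o$r, tolerance = 1e-12)
  expect_equal(r$ci95, o$ci, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  expect_equal(geneset_correlation(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_equal(geneset_correlation(a, -a)$r, -1, tolerance = 1e-12)
  expect_error(geneset_correlation(a, rep(1, 5)), "constant")
  expect_error(geneset_correlation(a, b[1:4]), "length")
  set.seed(9)
  for (i in 1:100) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x)) + 0.3 * x
    r <- geneset_correlation(x, y)
    o <- oracle_pearson(x, y)
    expect_equal(r$r, o$r, tolerance = 1e-12)
    expect_equal(r$ci95, o$ci, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }
})

test_that("group correlation reproduces a scalar reference on a hand-built fixture", {
  # 6 genes x 9 cells in 3 groups of 3; identical cells within groups
  gm <- cbind(a = c(1, 5, 2, 0, 7, 3),
              b = c(2, 4, 2, 1, 6, 3),
              c = c(9, 0, 5, 4, 1, 8))
  m <- gm[, rep(c("a", "b", "c"), each = 3)]
  norm <- make_norm(m)
  groups <- rep(c("a", "b", "c"), each = 3)
  cm <- group_correlation(norm, groups, top_n = 4)
  sds <- apply(gm, 1, sd)
  keep <- head(order(-sds, sprintf("g%04d", 1:6)), 4)
  ref <- cor(gm[keep, ])
  expect_equal(unclass(cm)[1:3, 1:3], ref, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(attr(cm, "genes"), sprintf("g%04d", keep))
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  # identical group mean vectors give r = 1
  m2 <- gm[, c("a", "a", "a", "a")]
  cm2 <- group_correlation(make_norm(m2), c("g1", "g1", "g2", "g2"),
                           top_n = 6)
  expect_equal(unname(cm2["g1", "g2"]), 1, tolerance = 1e-12)
  expect_error(group_correlation(norm, rep("one", 9)), ">= 2 groups")
  expect_warning(group_correlation(norm, groups, top_n = 50), "using all")
})

test_that("group correlation permutes consistently with group order", {
  set.seed(4)
  m <- matrix(rexp(40 * 12), 40, 12)
  groups <- rep(c("x", "y", "z"), each = 4)
  norm <- make_norm(m)
  cm <- group_correlation(norm, groups, top_n = 20)
  perm <- c(9:12, 1:8)
  norm2 <- make_norm(m[, perm])
  cm2 <- group_correlation(norm2, groups[perm], top_n = 20)
  expect_equal(cm2[c("x", "y", "z"), c("x", "y", "z")],
               cm[c("x", "y", "z"), c("x", "y", "z")], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("gene sets load from GMT and plain list files", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), gmt)
  sets <- read_gene_sets(gmt)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setB, c("g2", "g4"))
  txt <- tempfile(fileext = ".txt")
  writeLines(c("g1", "g5", "g1"), txt)
  sets2 <- read_gene_sets(txt)
  expect_length(sets2, 1)
  expect_identical(sets2[[1]], c("g1", "g5"))
  expect_error(read_gene_sets(tempfile()), "not found")
})
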