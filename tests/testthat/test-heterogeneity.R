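test_that("mutual information and NMI match analytic values", {
  x <- c(0L, 0L, 1L, 1L)
  y <- c(0L, 1L, 0L, 1L)
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(x, y), 0, tolerance = 1e-12)
  expect_equal(nmi(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L)), 1, tolerance = 1e-12)
  expect_equal(nmi(x, y), 0, tolerance = 1e-12)
  # three-bin case, frozen from the enumeration oracle:
  # I = ln 2, H(x) = H(y) = 1.5 ln 2, NMI = 2/3
  x2 <- c(0L, 0L, 1L, 2L)
  y2 <- c(0L, 1L, 1L, 2L)
  expect_equal(mutual_information(x2, y2), log(2), tolerance = 1e-12)
  expect_equal(nmi(x2, y2), 2 / 3, tolerance = 1e-12)
  expect_warning(v <- nmi(c(1L, 1L, 1L), c(0L, 1L, 2L)), "zero entropy")
  expect_identical(v, 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI/NMI agree with the brute-force oracle and respect bounds and symmetry", {
  set.seed(77)
  for (i in 1:200) {
    L <- sample(3:50, 1)
    B <- sample(2:10, 1)
    x <- sample.int(B, L, replace = TRUE) - 1L
    y <- sample.int(B, L, replace = TRUE) - 1L
    I <- mutual_information(x, y)
    expect_lt(abs(I - oracle_mi(x, y)), 1e-12)
    expect_gte(I, 0)
    expect_lte(I, min(oracle_entropy(x), oracle_entropy(y)) + 1e-12)
    if (oracle_entropy(x) > 0 && oracle_entropy(y) > 0) {
      n <- nmi(x, y)
      expect_lt(abs(n - oracle_nmi(x, y)), 1e-12)
      expect_identical(n, nmi(y, x))
      expect_gte(n, 0)
      expect_lte(n, 1 + 1e-12)
    }
  }
})

test_that("bin-shuffling noise added to one profile never increases expected NMI", {
  set.seed(31)
  x <- sample.int(10, 400, replace = TRUE) - 1L
  y <- x
  flip <- sample(400, 120)
  y[flip] <- sample.int(10, 120, replace = TRUE) - 1L  # correlated pair
  base <- nmi(x, y)
  noised <- replicate(100, {
    y2 <- y
    k <- sample(400, 80)
    y2[k] <- y2[sample(k)]     # shuffle a subset of y's bins
    nmi(x, y2)
  })
  expect_lt(mean(noised), base)
})

test_that("discretization follows the stated binning contract", {
  m <- rbind(rep(2.5, 10), 0:9, c(0.0, 0.49, 0.51, 1.0, rep(0, 6)))
  x <- make_counts(m + 1)          # keep totals positive
  norm <- normalize_counts(x)
  norm$mat <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  dimnames(norm$mat) <- dimnames(x$counts)
  d10 <- discretize(norm, c("g0001", "g0002"), n_bins = 10)
  expect_true(all(d10$bins["g0001", ] == 0L))          # constant gene
  expect_null(d10$edges[["g0001"]])
  expect_identical(unname(d10$bins["g0002", ]), 0:9)   # exact grid
  d2 <- discretize(norm, "g0003", n_bins = 2)
  expect_identical(unname(d2$bins[1, 1:4]), c(0L, 0L, 1L, 1L))
  expect_true(all(vapply(Filter(Negate(is.null), d2$edges),
                         function(e) all(diff(e) > 0), logical(1))))
  expect_error(discretize(norm, character(0)), "empty")
  expect_error(discretize(norm, "absent"), "absent")
})

test_that("marker ranking matches wilcox.test and handles separations and null genes", {
  set.seed(5)
  m <- matrix(rpois(5 * 40, 5), 5, 40)
  cl <- rep(c("A", "B"), each = 20)
  m[1, cl == "A"] <- m[1, cl == "A"] + 30   # strongly up in A
  m[2, ] <- rep(c(3, 7), 20)                # identically distributed
  x <- make_counts(m + 1, cells = data.frame(cell_type = cl))
  norm <- normalize_counts(x)
  # test directly on the raw values so gene 2 stays exactly null
  norm$mat <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  dimnames(norm$mat) <- dimnames(x$counts)
  mk <- rank_markers(norm, cl, top_m = 5)
  expect_identical(mk$A$gene[1], "g0001")
  expect_identical(mk$A$gene[5], "g0002")   # null gene ranks last
  expect_gt(mk$A$p_value[5], 0.9)
  # p-values equal the classical normal-approximation rank-sum test
  v <- as.matrix(norm$mat)
  for (g in 1:5) {
    ref <- suppressWarnings(
      wilcox.test(v[g, cl == "A"], v[g, cl == "B"], exact = FALSE,
                  correct = FALSE)$p.value)
    got <- mk$A$p_value[match(rownames(v)[g], mk$A$gene)]
    expect_equal(got, ref, tolerance = 1e-10)
  }
  expect_warning(rank_markers(norm, c(rep("A", 39), "C"), top_m = 2),
                 "< 2 cells")
})

test_that("panel construction unions marker and component genes deterministically", {
  markers <- list(c1 = c("a", "b", "c"), c2 = c("b", "d"))
  loadings <- matrix(c(0.9, 0.8, 0.1, 0.3, 0.2, 0.1), 3, 2,
                     dimnames = list(c("c", "e", "f"), NULL))
  p <- build_panel(markers, loadings, top_m = 3, top_k = 2, n_components = 1)
  expect_identical(p$gene, c("a", "b", "c", "d", "e"))
  expect_identical(p$source[4:5], c("cluster:c2", "component:1"))
  # identical lists collapse to one
  p2 <- build_panel(list(c1 = c("a", "b"), c2 = c("a", "b")))
  expect_identical(p2$gene, c("a", "b"))
  # disjoint blocks just concatenate
  p3 <- build_panel(list(c1 = c("a", "b", "c"), c2 = c("d", "e", "f")),
                    matrix(1:4, 2, 2, dimnames = list(c("x", "y"), NULL)),
                    top_m = 3, top_k = 2, n_components = 2)
  expect_identical(nrow(p3), 8L)
})

test_that("stage heterogeneity is deterministic and exact on degenerate stages", {
  # a stage of identical, non-constant cells has every pairwise NMI = 1
  bins <- cbind(matrix(rep(c(0L, 1L, 2L, 3L), 25), 100, 8),
                matrix(sample.int(4, 800, replace = TRUE) - 1L, 100, 8))
  disc <- structure(list(bins = bins, n_bins = 4L, edges = NULL,
                         method = "width"), class = "disc_matrix")
  stages <- rep(c("same", "rand"), each = 8)
  het <- suppressWarnings(
    stage_heterogeneity(disc, stages, n_cells = 8, n_draws = 10, seed = 1))
  expect_equal(max(abs(het$medians$same - 1)), 0, tolerance = 1e-12)
  expect_lt(median(het$medians$rand), 1)
  het2 <- suppressWarnings(
    stage_heterogeneity(disc, stages, n_cells = 8, n_draws = 10, seed = 1))
  expect_identical(het$medians, het2$medians)
  # undersized stage: all cells used in every draw, with a warning
  disc_same <- disc
  disc_same$bins <- bins[, 1:8]
  expect_warning(
    h3 <- stage_heterogeneity(disc_same, rep("same", 8), n_cells = 50,
                              n_draws = 3, seed = 1),
    "using all")
  expect_identical(length(unique(h3$medians$same)), 1L)
  expect_error(stage_heterogeneity(disc, rep("s", 16), n_cells = 8,
                                   n_draws = 0, seed = 1), "n_draws")
})

test_that("the C++ all-pairs kernel agrees with the R implementation", {
  set.seed(12)
  bins <- matrix(sample.int(6, 30 * 12, replace = TRUE) - 1L, 30, 12)
  cpp <- stagehet:::cpp_pairwise_nmi(bins, 6L)
  k <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    k <- k + 1
    expect_equal(cpp[k], suppressWarnings(nmi(bins[, i], bins[, j])),
                 tolerance = 1e-12)
  }
  # draw medians equal the median of the R pairwise values
  idx <- matrix(c(1:8, 5:12), 2, 8, byrow = TRUE)
  res <- stagehet:::cpp_draw_median_nmi(bins, idx, 6L)
  for (d in 1:2) {
    vals <- combn(idx[d, ], 2, function(p) {
      suppressWarnings(nmi(bins[, p[1]], bins[, p[2]]))
    })
    expect_equal(res$medians[d], median(vals), tolerance = 1e-12)
  }
})

test_that("median NMI rank-order inverts the stage noise rank-order (parameter recovery)", {
  noise <- c(0.2, 0.6, 1.0, 1.4)
  for (seed in c(2, 7, 19)) {
    sim <- simulate_counts(sim_config(
      n_genes = 800, n_mito_genes = 20, stages = paste0("s", 1:4),
      cells_per_stage = 150, stage_noise_sd = noise, seed = seed))
    norm <- normalize_counts(sim)
    disc <- discretize(norm, rownames(norm$mat), 10)
    het <- stage_heterogeneity(disc, sim$cells, n_cells = 60, n_draws = 30,
                               seed = seed)
    meds <- vapply(het$medians, median, numeric(1))
    expect_identical(unname(rank(meds)), rev(rank(noise)),
                     label = sprintf("seed %d rank order", seed))
  }
})

test_that("stage comparisons behave on degenerate and hand-computable inputs", {
  mk_res <- function(a, b) {
    structure(list(medians = list(s1 = a, s2 = b),
                   n_cells_used = c(s1 = 10, s2 = 10),
                   zero_entropy_pairs = c(s1 = 0, s2 = 0),
                   params = list(n_cells = 10, n_draws = length(a), seed = 1,
                                 n_bins = 10)), class = "stage_nmi")
  }
  ident <- mk_res(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  ct <- compare_stages(ident, "t")
  expect_equal(ct$p_value, 1)
  expect_equal(ct$statistic, 0)
  # exact Mann-Whitney on completely separated constant vectors:
  # U = 25 and the two-sided exact p over all C(10,5) assignments is 2/252
  mw <- compare_stages(mk_res(rep(1, 5), rep(0, 5)), "mann-whitney")
  expect_equal(mw$statistic, 25)
  expect_equal(mw$p_value, 2 / 252, tolerance = 1e-12)
  expect_identical(mw$direction, 1)
  expect_error(compare_stages(ident, "bogus"))
  expect_match(attr(ct, "caveat"), "not independent")
})
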