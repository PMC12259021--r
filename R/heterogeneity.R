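#' Discretize a normalized expression matrix over a feature panel
#'
#' Each panel gene's values across all cells are mapped to integer bins
#' `0..n_bins-1`. With `method = "width"` (default) bins are equal-width over
#' the observed `[min, max]`; the maximum value falls in the top bin
#' (right-closed). With `method = "quantile"` bin edges are the empirical
#' quantiles. Genes constant across cells map every cell to bin 0.
#'
#' @param norm an `sc_norm` object.
#' @param panel a `feature_panel` from [build_panel()], or a character vector
#'   of gene IDs present in `norm`.
#' @param n_bins number of bins (default 10, must be >= 2).
#' @param method binning rule, `"width"` or `"quantile"`.
#' @return object of class `disc_matrix`: list with `bins` (panel genes x
#'   cells integer matrix, entries in `0..n_bins-1`), `edges` (per-gene bin
#'   edges; `NULL` for constant genes), `n_bins`, `method`.
#' @export
discretize <- function(norm, panel, n_bins = 10L,
                       method = c("width", "quantile")) {
  if (!inherits(norm, "sc_norm")) stopf("norm must be an sc_norm object")
  method <- match.arg(method)
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  genes <- if (inherits(panel, "feature_panel")) panel$gene else as.character(panel)
  if (length(genes) == 0L) stopf("empty feature panel")
  missing <- setdiff(genes, rownames(norm$mat))
  if (length(missing)) {
    stopf("panel gene(s) absent from matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  X <- as.matrix(norm$mat[genes, , drop = FALSE])
  bins <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  edges <- vector("list", nrow(X))
  names(edges) <- genes
  for (g in seq_len(nrow(X))) {
    v <- X[g, ]
    if (method == "width") {
      lo <- min(v); hi <- max(v)
      if (hi <= lo) next  # constant: all bin 0, no edges
      e <- seq(lo, hi, length.out = n_bins + 1L)
    } else {
      e <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7))
      if (length(e) < 2L) next
    }
    bins[g, ] <- findInterval(v, e, all.inside = TRUE) - 1L
    edges[[g]] <- e
  }
  structure(list(bins = bins, edges = edges, n_bins = n_bins, method = method),
            class = "disc_matrix")
}

entropy_nats <- function(x) {
  p <- tabulate(match(x, unique(x))) / length(x)
  -sum(p * log(p))
}

#' Mutual information between two discretized profiles
#'
#' `I(x, y) = sum_x sum_y p(x, y) log[ p(x, y) / (p(x) p(y)) ]` in nats,
#' where `p(x)` and `p(y)` are the empirical bin-frequency distributions of
#' each profile over its entries (here: the panel genes of one cell) and
#' `p(x, y)` is the empirical joint distribution of aligned bin pairs.
#' Zero-probability joint cells contribute 0.
#'
#' @param x,y integer (or factor-like) vectors of equal length.
#' @return non-negative mutual information in nats.
#' @seealso [nmi()]
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) == 0L) stopf("profiles must be non-empty")
  L <- length(x)
  jt <- table(x, y) / L
  px <- rowSums(jt)
  py <- colSums(jt)
  nz <- jt > 0
  I <- sum(jt[nz] * log(jt[nz] / outer(px, py)[nz]))
  max(I, 0)
}

#' Normalized mutual information between two discretized profiles
#'
#' `NMI(x, y) = I(x, y) / sqrt(H(x) H(y))`, in `[0, 1]`; `NMI(x, x) = 1`
#' whenever `x` is non-constant. If either profile is constant (zero
#' entropy) the value is defined as 0, with a warning, so that medians over
#' many pairs remain computable.
#'
#' @inheritParams mutual_information
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  Hx <- entropy_nats(x)
  Hy <- entropy_nats(y)
  if (Hx <= 0 || Hy <= 0) {
    warnf("constant profile has zero entropy; NMI defined as 0")
    return(0)
  }
  min(mutual_information(x, y) / sqrt(Hx * Hy), 1)
}

#' Within-stage heterogeneity by subsampled median pairwise NMI
#'
#' For each stage, `n_draws` subsamples of `n_cells` cells are taken without
#' replacement; within each subsample all pairwise NMIs between discretized
#' cell profiles are computed and their median recorded. The distribution of
#' these draw medians is the stage's homogeneity profile: high medians mean
#' transcriptionally alike cells, falling medians mean growing
#' cell-to-cell heterogeneity.
#'
#' Each stage uses a sub-seed derived deterministically from `seed` and the
#' stage's position, so adding or dropping a stage does not perturb the
#' draws of the others. If a stage has fewer than `n_cells` cells, all its
#' cells are used in every draw (the identical draw is computed once and
#' replicated, with a warning); stages with fewer than 2 cells are excluded.
#'
#' @param disc a `disc_matrix` from [discretize()].
#' @param cells per-cell stage labels (length `ncol(disc$bins)`), or a
#'   data.frame with a `stage` column (e.g. the `cells` table).
#' @param n_cells cells per subsample (default 100).
#' @param n_draws number of subsamples per stage (default 500).
#' @param seed integer seed for the subsampling streams.
#' @return object of class `stage_nmi`: list with `medians` (named list,
#'   per stage, of `n_draws` draw-median NMI values), `n_cells_used`,
#'   `zero_entropy_pairs`, and `params`.
#' @export
stage_heterogeneity <- function(disc, cells, n_cells = 100L, n_draws = 500L,
                                seed = 1L) {
  if (!inherits(disc, "disc_matrix")) stopf("disc must be a disc_matrix")
  stage <- if (is.data.frame(cells)) cells$stage else as.character(cells)
  if (length(stage) != ncol(disc$bins)) {
    stopf("need one stage label per cell (%d cells, %d labels)",
          ncol(disc$bins), length(stage))
  }
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  n_draws <- check_count(n_draws, "n_draws")
  seed <- check_count(seed, "seed", min = 0L)
  stages <- unique(stage)
  medians <- list()
  used <- integer(0)
  zep <- numeric(0)
  for (s in seq_along(stages)) {
    idx <- which(stage == stages[s])
    if (length(idx) < 2L) {
      warnf("stage '%s' has < 2 cells; excluded", stages[s])
      next
    }
    n_use <- min(n_cells, length(idx))
    if (n_use < n_cells) {
      warnf("stage '%s' has %d < %d cells; using all of them per draw",
            stages[s], length(idx), n_cells)
    }
    if (n_use == length(idx)) {
      # every draw is the same set: compute once, replicate
      imat <- matrix(idx, nrow = 1L)
      res <- cpp_draw_median_nmi(disc$bins, imat, disc$n_bins)
      med <- rep(res$medians, n_draws)
      nz <- res$n_zero_entropy_pairs * n_draws
    } else {
      imat <- with_seed(seed + 7919L * s, {
        t(vapply(seq_len(n_draws),
                 function(i) sort(idx[sample.int(length(idx), n_use)]),
                 integer(n_use)))
      })
      res <- cpp_draw_median_nmi(disc$bins, imat, disc$n_bins)
      med <- res$medians
      nz <- res$n_zero_entropy_pairs
    }
    medians[[stages[s]]] <- med
    used[stages[s]] <- n_use
    zep[stages[s]] <- nz
  }
  if (length(medians) == 0L) stopf("no stage with >= 2 cells")
  structure(list(medians = medians, n_cells_used = used,
                 zero_entropy_pairs = zep,
                 params = list(n_cells = n_cells, n_draws = n_draws,
                               seed = seed, n_bins = disc$n_bins)),
            class = "stage_nmi")
}

# Exact two-sided Mann-Whitney p-value by enumeration of all C(n1+n2, n1)
# group assignments of the pooled values (valid with ties).
mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  dev_obs <- abs(U_obs - mu)
  sets <- combn(length(pooled), n1)
  dev <- apply(sets, 2, function(ix) {
    abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - mu)
  })
  list(U = U_obs, p = mean(dev >= dev_obs - 1e-9))
}

#' Compare stage heterogeneity distributions pairwise
#'
#' Every pair of stages is compared on its draw-median NMI vectors, by a
#' two-tailed unpaired Student's t-test (default) or a Mann-Whitney test
#' (exact enumeration when the pooled size is <= 20, normal approximation
#' otherwise). Because draw medians are resampled from the same cells they
#' are not independent observations; the p-values are descriptive and the
#' result carries a `caveat` attribute saying so.
#'
#' @param result a `stage_nmi` from [stage_heterogeneity()].
#' @param method `"t"` or `"mann-whitney"`.
#' @return data.frame of class `stage_comparison` with columns `stage_a`,
#'   `stage_b`, `median_a`, `median_b`, `direction` (sign of
#'   `median_a - median_b`), `statistic`, `p_value`, `method`.
#' @export
compare_stages <- function(result, method = c("t", "mann-whitney")) {
  if (!inherits(result, "stage_nmi")) stopf("result must be a stage_nmi")
  method <- match.arg(method)
  stages <- names(result$medians)
  if (length(stages) < 2L) stopf("need >= 2 stages to compare")
  pairs <- combn(length(stages), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- result$medians[[pairs[1, k]]]
    b <- result$medians[[pairs[2, k]]]
    if (method == "t") {
      if (sd(a) == 0 && sd(b) == 0) {
        stat <- 0; p <- if (mean(a) == mean(b)) 1 else 0
      } else {
        tt <- t.test(a, b, var.equal = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
    } else {
      if (length(a) + length(b) <= 20L) {
        mw <- mw_exact(a, b)
        stat <- mw$U; p <- mw$p
      } else {
        wt <- wilcox.test(a, b, exact = FALSE)
        stat <- unname(wt$statistic); p <- wt$p.value
      }
    }
    data.frame(stage_a = stages[pairs[1, k]], stage_b = stages[pairs[2, k]],
               median_a = median(a), median_b = median(b),
               direction = sign(median(a) - median(b)),
               statistic = stat, p_value = p, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "caveat") <-
    "draw medians are resampled from the same cells and are not independent observations"
  class(out) <- c("stage_comparison", "data.frame")
  out
}

#' @export
print.stage_nmi <- function(x, ...) {
  cat(sprintf("<stage_nmi> %d stages, %d draws of %d cells, %d bins\n",
              length(x$medians), x$params$n_draws, x$params$n_cells,
              x$params$n_bins))
  for (s in names(x$medians)) {
    cat(sprintf("  %-12s median NMI %.4f  (IQR %.4f-%.4f, n_cells = %d)\n",
                s, median(x$medians[[s]]),
                quantile(x$medians[[s]], 0.25),
                quantile(x$medians[[s]], 0.75), x$n_cells_used[[s]]))
  }
  invisible(x)
}

#' @export
summary.stage_nmi <- function(object, ...) {
  data.frame(
    stage = names(object$medians),
    n_draws = lengths(object$medians),
    n_cells = as.integer(object$n_cells_used[names(object$medians)]),
    median_nmi = vapply(object$medians, median, numeric(1)),
    mean_nmi = vapply(object$medians, mean, numeric(1)),
    sd_nmi = vapply(object$medians, sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Boxplot of within-stage draw-median NMI distributions
#' @param x a `stage_nmi` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.stage_nmi <- function(x, ...) {
  graphics::boxplot(x$medians, ylab = "draw-median pairwise NMI",
                    xlab = "stage", ...)
  invisible(x)
}
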