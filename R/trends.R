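#' Fit a gene-expression trend along pseudotime with branch weights
#'
#' Weighted smooth regression of one gene's expression on pseudotime, the
#' standard way to summarize expression dynamics along a differentiation
#' branch: a generalized additive model with penalized cubic regression
#' splines, using each cell's branch probability as its observation weight,
#' evaluated on a regular pseudotime grid. Cells with zero weight are
#' excluded, so the fit equals the fit on the positive-weight subset.
#'
#' @param expression Numeric vector of normalized expression (one gene).
#' @param pseudotime Numeric vector in `[0, 1]`, same length.
#' @param weights Optional branch probabilities in `[0, 1]` (default: 1).
#' @param grid_size Number of grid points (default 500).
#' @param k Spline basis dimension (default 10; reduced when pseudotime has
#'   few unique values).
#' @param gene,branch,condition Optional identifiers carried in the result.
#' @return Object of class `gene_trend`: `grid`, `values`, `gene`, `branch`,
#'   `condition`.
#' @export
fit_trend <- function(expression, pseudotime, weights = NULL,
                      grid_size = 500L, k = 10L,
                      gene = NA_character_, branch = NA_character_,
                      condition = NA_character_) {
  n <- length(expression)
  if (length(pseudotime) != n) stop("expression/pseudotime length mismatch")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  .stop_if_not_prob(weights, "weights")
  keep <- weights > 0
  if (!any(keep)) stop("all branch weights are zero")
  y <- expression[keep]
  x <- pseudotime[keep]
  w <- weights[keep]
  if (length(y) < 30L) stop("need at least 30 cells with positive weight")
  ux <- unique(x)
  if (length(ux) < 2L || diff(range(x)) < 1e-12)
    stop("pseudotime is degenerate (constant)")
  kk <- max(4L, min(as.integer(k), length(ux) - 1L))
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = kk), weights = w,
                   method = "GCV.Cp")
  grid <- seq(min(x), max(x), length.out = grid_size)
  vals <- as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
  structure(list(grid = grid, values = vals, gene = gene, branch = branch,
                 condition = condition,
                 data = data.frame(pseudotime = x, expression = y,
                                   weight = w)),
            class = "gene_trend")
}

#' Cluster gene trends by shape
#'
#' Z-scores each trend across the grid and clusters genes by correlation
#' distance with average-linkage hierarchical clustering cut at `k`.
#' Constant (flat) trends cannot be z-scored and are assigned to their own
#' `"flat"` group with a warning.
#'
#' @param trends Named list of `gene_trend`s sharing one grid.
#' @param k Number of clusters (>= 2).
#' @return Named character vector gene -> cluster (`"1" ... "k"` or
#'   `"flat"`).
#' @export
cluster_trends <- function(trends, k) {
  if (k < 2) stop("k must be >= 2")
  if (is.null(names(trends)))
    names(trends) <- vapply(trends, function(t) t$gene, "")
  grids <- lapply(trends, function(t) t$grid)
  for (g in grids[-1L]) {
    if (length(g) != length(grids[[1L]]) ||
        max(abs(g - grids[[1L]])) > 1e-9)
      stop("all trends must share the same grid")
  }
  mat <- do.call(rbind, lapply(trends, function(t) t$values))
  sds <- apply(mat, 1L, stats::sd)
  flat <- sds < 1e-12
  if (any(flat))
    warning(sprintf("%d constant trend(s) assigned to the 'flat' group",
                    sum(flat)))
  out <- setNames(rep("flat", length(trends)), names(trends))
  live <- which(!flat)
  if (length(live)) {
    if (length(live) == 1L) {
      out[live] <- "1"
    } else {
      z <- t(scale(t(mat[live, , drop = FALSE])))
      d <- stats::as.dist(1 - stats::cor(t(z)))
      hc <- stats::hclust(d, method = "average")
      cl <- stats::cutree(hc, k = min(k, length(live)))
      out[live] <- as.character(cl)
    }
  }
  out
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n+m, n)
# assignments of the pooled (mid)ranks to group a. Handles ties naturally.
.wilcoxon_exact_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  W <- colSums(matrix(r[combs], nrow = n))
  eps <- 1e-9
  p_le <- mean(W <= w_obs + eps)
  p_ge <- mean(W >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sample Wilcoxon comparison of two gene expression trends
#'
#' Rank-sum test for a difference in a gene's expression along pseudotime
#' between two conditions. With `values = "cells"` (default) the test
#' compares the per-cell expression values that entered each fit — the
#' cells are independent observations, so the test is calibrated. With
#' `values = "grid"` it compares the fitted grid curves instead; grid
#' points of a smooth share their estimation noise, which makes that
#' variant anti-conservative on fine grids, so it is kept for
#' curve-summary comparisons rather than inference. The null is enumerated
#' exactly when both vectors have at most `exact_max` values; otherwise
#' the normal approximation with tie and continuity correction is used.
#' Two-sided.
#'
#' @param trend_a,trend_b `gene_trend`s on a shared grid, or plain numeric
#'   vectors (compared directly).
#' @param values `"cells"` (per-cell expression, default) or `"grid"`
#'   (fitted grid values).
#' @param exact_max Largest per-group size for exact enumeration (default
#'   10).
#' @return Two-sided p-value.
#' @export
compare_trends <- function(trend_a, trend_b, values = c("cells", "grid"),
                           exact_max = 10L) {
  values <- match.arg(values)
  pick <- function(tr) {
    if (!inherits(tr, "gene_trend")) return(tr)
    if (values == "cells" && !is.null(tr$data)) tr$data$expression
    else tr$values
  }
  va <- pick(trend_a)
  vb <- pick(trend_b)
  if (values == "grid" &&
      inherits(trend_a, "gene_trend") && inherits(trend_b, "gene_trend")) {
    if (length(trend_a$grid) != length(trend_b$grid))
      stop("trends are evaluated on different grids")
  }
  if (!length(va) || !length(vb)) stop("empty trend values")
  if (identical(va, vb)) return(1)
  if (length(va) <= exact_max && length(vb) <= exact_max) {
    .wilcoxon_exact_p(va, vb)
  } else {
    suppressWarnings(
      stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Compare a matched set of trends between two conditions
#'
#' Runs [compare_trends()] per gene, Holm-adjusts across the gene set, and
#' assigns significance tiers: `***` adjusted p < 0.001, `**` < 0.01,
#' `*` < 0.05, `NS` otherwise.
#'
#' @param trends_a,trends_b Named lists of `gene_trend`s (matched by name).
#' @param values Passed to [compare_trends()] (default `"cells"`).
#' @return Data.frame: `gene`, `p_raw`, `p_adjusted`, `tier`.
#' @export
compare_trend_set <- function(trends_a, trends_b,
                              values = c("cells", "grid")) {
  values <- match.arg(values)
  genes <- intersect(names(trends_a), names(trends_b))
  if (!length(genes)) stop("no shared genes between trend sets")
  p_raw <- vapply(genes, function(g)
    compare_trends(trends_a[[g]], trends_b[[g]], values = values), 0)
  p_adj <- holm_adjust(p_raw)
  tier <- ifelse(p_adj < 0.001, "***",
          ifelse(p_adj < 0.01, "**",
          ifelse(p_adj < 0.05, "*", "NS")))
  data.frame(gene = genes, p_raw = unname(p_raw),
             p_adjusted = unname(p_adj), tier = unname(tier),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit trends for many genes along one branch
#'
#' Convenience wrapper calling [fit_trend()] for each gene of a normalized
#' matrix with a shared trajectory.
#'
#' @param normalized A `normalized_matrix`.
#' @param genes Genes to fit.
#' @param pseudotime Named numeric vector of pseudotime (by cell id).
#' @param weights Optional named branch-probability vector (by cell id).
#' @param branch,condition Identifiers stored on each trend.
#' @param grid_size Grid size passed to [fit_trend()].
#' @return Named list of `gene_trend`s.
#' @export
fit_trend_set <- function(normalized, genes, pseudotime, weights = NULL,
                          branch = NA_character_, condition = NA_character_,
                          grid_size = 500L) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  cells <- intersect(colnames(normalized$values), names(pseudotime))
  if (!length(cells)) stop("no cells shared between matrix and trajectory")
  pt <- pseudotime[cells]
  w <- if (is.null(weights)) NULL else weights[cells]
  missing_genes <- setdiff(genes, rownames(normalized$values))
  if (length(missing_genes))
    stop(sprintf("genes absent from matrix: %s",
                 paste(head(missing_genes, 5), collapse = ", ")))
  out <- lapply(genes, function(g) {
    fit_trend(as.numeric(normalized$values[g, cells]), pt, weights = w,
              grid_size = grid_size, gene = g, branch = branch,
              condition = condition)
  })
  names(out) <- genes
  out
}
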