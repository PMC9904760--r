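#' Quality-control thresholds for cell filtering
#'
#' Per-sample ceilings on detected genes and UMIs (the doublet filter) and
#' bounds on the mitochondrial count percentage. High mitochondrial content
#' flags dying cells; an optional lower bound excludes anomalous cells with
#' almost no mitochondrial reads.
#'
#' @param max_genes_per_cell Maximum detected genes per cell.
#' @param max_umis_per_cell Maximum total UMIs per cell.
#' @param mito_max_pct Maximum mitochondrial percentage (commonly 5 or 10).
#' @param mito_min_pct Optional minimum mitochondrial percentage (e.g. 1).
#' @param mito_gene_pattern Regex identifying mitochondrial genes by name.
#' @param mito_genes Optional explicit mitochondrial gene list (overrides
#'   the pattern).
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_genes_per_cell = Inf,
                          max_umis_per_cell = Inf,
                          mito_max_pct = 5,
                          mito_min_pct = NULL,
                          mito_gene_pattern = "^MT-",
                          mito_genes = NULL) {
  if (max_genes_per_cell <= 0 || max_umis_per_cell <= 0)
    stop("gene/UMI ceilings must be positive")
  if (mito_max_pct <= 0 || mito_max_pct > 100)
    stop("mito_max_pct must lie in (0, 100]")
  if (!is.null(mito_min_pct)) {
    if (mito_min_pct < 0 || mito_min_pct >= 100)
      stop("mito_min_pct must lie in [0, 100)")
    if (mito_min_pct >= mito_max_pct)
      stop("mito_min_pct must be below mito_max_pct")
  }
  structure(list(max_genes_per_cell = max_genes_per_cell,
                 max_umis_per_cell = max_umis_per_cell,
                 mito_max_pct = mito_max_pct, mito_min_pct = mito_min_pct,
                 mito_gene_pattern = mito_gene_pattern,
                 mito_genes = mito_genes),
            class = "qc_thresholds")
}

#' Suggest per-sample gene/UMI ceilings
#'
#' Data-driven helper reproducing the practice of inspecting the per-sample
#' distributions of detected genes and UMIs and cutting at a high quantile
#' to remove presumptive doublets.
#'
#' @param counts genes x cells count matrix.
#' @param quantile Quantile for the ceilings (default 0.99).
#' @return List with `max_genes_per_cell` and `max_umis_per_cell`.
#' @export
suggest_thresholds <- function(counts, quantile = 0.99) {
  counts <- .as_sparse(counts)
  n_genes <- Matrix::colSums(counts > 0)
  n_umis <- Matrix::colSums(counts)
  list(max_genes_per_cell = unname(stats::quantile(n_genes, quantile)),
       max_umis_per_cell = unname(stats::quantile(n_umis, quantile)))
}

#' Filter cells on gene/UMI ceilings and mitochondrial percentage
#'
#' Retains exactly the cells with detected genes \eqn{\le} `max_genes`, total
#' UMIs \eqn{\le} `max_umis`, mitochondrial percentage \eqn{\le}
#' `mito_max_pct` and (if set) \eqn{\ge} `mito_min_pct`. Zero-count cells are
#' removed with reason `"empty"`. If no mitochondrial genes are found the
#' mitochondrial rules are skipped with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param thresholds A [qc_thresholds()].
#' @return List with `counts` (retained cells) and `report`, a per-cell
#'   data.frame (`cell_id`, `n_genes`, `n_umis`, `pct_mito`, `kept`,
#'   `reason`; failing rules comma-joined, empty when kept).
#' @export
filter_cells <- function(counts, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- .assert_counts(.as_sparse(counts))
  n_genes <- Matrix::colSums(counts > 0)
  n_umis <- Matrix::colSums(counts)
  mito <- thresholds$mito_genes
  if (is.null(mito))
    mito <- grep(thresholds$mito_gene_pattern, rownames(counts), value = TRUE)
  mito <- intersect(mito, rownames(counts))
  mito_rules <- length(mito) > 0
  if (!mito_rules)
    warning("no mitochondrial genes found; mitochondrial rules skipped")
  pct_mito <- if (mito_rules) {
    100 * Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(n_umis, 1)
  } else rep(NA_real_, ncol(counts))

  reasons <- vector("list", ncol(counts))
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(n_umis == 0, "empty")
  add(n_umis > 0 & n_genes > thresholds$max_genes_per_cell, "max_genes")
  add(n_umis > thresholds$max_umis_per_cell, "max_umis")
  if (mito_rules) {
    add(n_umis > 0 & pct_mito > thresholds$mito_max_pct, "high_mito")
    if (!is.null(thresholds$mito_min_pct))
      add(n_umis > 0 & pct_mito < thresholds$mito_min_pct, "low_mito")
  }
  kept <- lengths(reasons) == 0L
  report <- data.frame(
    cell_id = colnames(counts), n_genes = as.integer(n_genes),
    n_umis = as.numeric(n_umis), pct_mito = as.numeric(pct_mito),
    kept = kept,
    reason = vapply(reasons, function(r) paste(r, collapse = ","), ""),
    stringsAsFactors = FALSE)
  list(counts = counts[, kept, drop = FALSE], report = report)
}

#' Library-size normalization with log transform
#'
#' Divides gene counts by the total expression per cell, multiplies by a
#' scaling factor (default 10,000) and log-transforms:
#' `value[g, c] = ln(1 + count[g, c] * scale_factor / library_size_c)`.
#'
#' @param counts genes x cells count matrix; every cell must have a positive
#'   total count.
#' @param scale_factor Positive scaling factor.
#' @return Object of class `normalized_matrix`: list with `values` (sparse),
#'   `library_sizes` (named), `scale_factor`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- .assert_counts(.as_sparse(counts))
  if (scale_factor <= 0) stop("scale_factor must be positive")
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stop(sprintf("zero library size for cell(s): %s",
                 paste(head(colnames(counts)[lib == 0], 5), collapse = ", ")))
  values <- counts
  # scale the nonzeros column-wise, then log1p (zeros stay zero)
  col_of <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  values@x <- log1p(counts@x * scale_factor / lib[col_of])
  structure(list(values = values, library_sizes = setNames(lib, colnames(counts)),
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Invert [log_normalize()]
#'
#' Reconstructs raw counts from a normalized matrix using the stored library
#' sizes: `count = (exp(value) - 1) * library_size / scale_factor`.
#'
#' @param normalized A `normalized_matrix`.
#' @return genes x cells sparse matrix of counts.
#' @export
denormalize <- function(normalized) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  v <- normalized$values
  col_of <- rep.int(seq_len(ncol(v)), diff(v@p))
  v@x <- expm1(v@x) * normalized$library_sizes[col_of] /
    normalized$scale_factor
  v
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by the variance-stabilizing-transformation criterion: a local
#' polynomial curve of `log10(variance)` on `log10(mean)` is fitted over raw
#' counts, each gene's counts are standardized by the predicted standard
#' deviation with values clipped at `sqrt(n_cells)`, and genes are ranked by
#' the variance of the standardized values.
#'
#' @param counts genes x cells raw count matrix.
#' @param n_genes Number of genes to return (default 2000); saturates with a
#'   warning when fewer genes are available.
#' @param loess_span Span of the mean-variance curve fit (default 0.3).
#' @return Character vector of gene names, ranked by decreasing standardized
#'   variance; the `standardized_variance` attribute carries the full ranking.
#' @export
select_hvg <- function(counts, n_genes = 2000, loess_span = 0.3) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  counts <- .assert_counts(.as_sparse(counts))
  n_cells <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  # gene-wise variance on sparse data: E[x^2] - mu^2, with Bessel correction
  sq <- counts
  sq@x <- sq@x^2
  v <- (Matrix::rowSums(sq) - n_cells * mu^2) / (n_cells - 1)
  ok <- v > 0 & mu > 0
  if (sum(ok) < 3) stop("need at least 3 genes with positive variance")

  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span)
  exp_sd <- rep(0, length(mu))
  exp_sd[ok] <- sqrt(10^stats::predict(fit))
  clip <- sqrt(n_cells)

  # standardized variance with upper clipping, computed sparsely:
  # zeros contribute (0 - mu)/sd each, nonzeros their own clipped z-score
  tc <- Matrix::t(counts)
  p <- tc@p
  xv <- tc@x
  vstd <- numeric(length(mu))
  for (g in which(ok)) {
    nn <- p[g + 1L] - p[g]
    z0 <- min(clip, -mu[g] / exp_sd[g])
    ssq <- (n_cells - nn) * z0^2
    if (nn > 0) {
      z <- (xv[(p[g] + 1L):p[g + 1L]] - mu[g]) / exp_sd[g]
      z[z > clip] <- clip
      ssq <- ssq + sum(z^2)
    }
    vstd[g] <- ssq / (n_cells - 1)
  }
  names(vstd) <- rownames(counts)

  ord <- order(-vstd, rownames(counts))
  n_avail <- nrow(counts)
  if (n_genes > n_avail) {
    warning(sprintf("requested %d genes but only %d available", n_genes,
                    n_avail))
    n_genes <- n_avail
  }
  out <- rownames(counts)[ord][seq_len(n_genes)]
  attr(out, "standardized_variance") <- vstd[ord]
  out
}
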