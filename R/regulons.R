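#' Remove batch effects from a regulon activity (AUC) matrix
#'
#' Estimates per-regulon additive batch offsets by least squares (batch main
#' effects) and removes them, preserving each regulon's grand mean across
#' cells. With a single batch the matrix is returned unchanged.
#'
#' @param auc Regulons x cells numeric matrix (or an `auc_matrix`).
#' @param batches Per-cell batch labels (default: taken from the
#'   `auc_matrix`).
#' @return Same shape as the input; an `auc_matrix` input is returned with
#'   corrected `values`.
#' @export
batch_center <- function(auc, batches = NULL) {
  is_obj <- inherits(auc, "auc_matrix")
  vals <- if (is_obj) auc$values else auc
  if (is.null(batches)) {
    if (!is_obj) stop("batches must be supplied for a plain matrix")
    batches <- auc$batches
  }
  if (length(batches) != ncol(vals)) stop("one batch label per cell required")
  batches <- factor(batches)
  if (nlevels(batches) < 1L) stop("need at least one batch")
  sizes <- table(batches)
  if (any(sizes < 2L))
    warning("batch with fewer than 2 cells; offset still estimated")
  if (nlevels(batches) > 1L) {
    grand <- rowMeans(vals)
    corrected <- limma::removeBatchEffect(vals, batch = batches)
    corrected <- corrected + (grand - rowMeans(corrected))
  } else {
    corrected <- vals
  }
  if (is_obj) {
    auc$values <- corrected
    auc
  } else corrected
}

# Posterior-0.5 crossing between the two component means of a univariate
# two-component Gaussian mixture.
.gmm_threshold <- function(pro, mean, sd) {
  o <- order(mean)
  pro <- pro[o]; mean <- mean[o]; sd <- sd[o]
  post_hi <- function(x) {
    d1 <- pro[1L] * stats::dnorm(x, mean[1L], sd[1L])
    d2 <- pro[2L] * stats::dnorm(x, mean[2L], sd[2L])
    d2 / (d1 + d2) - 0.5
  }
  lo <- mean[1L]; hi <- mean[2L]
  if (post_hi(lo) * post_hi(hi) < 0) {
    stats::uniroot(post_hi, c(lo, hi))$root
  } else {
    (lo + hi) / 2
  }
}

#' Binarize regulon activity with a bimodal Gaussian mixture
#'
#' Per regulon, fits a two-component univariate Gaussian mixture to the AUC
#' values; the on/off threshold is the value where the posterior
#' responsibility crosses 0.5 between the component means, and a cell is
#' active (1) iff its value strictly exceeds the threshold. When model
#' selection (BIC) favors a single component, or the regulon is constant,
#' all cells are set to 0 with a warning.
#'
#' @param auc Regulons x cells matrix (or an `auc_matrix`; corrected values
#'   are used as-is).
#' @param min_cells Minimum number of cells required (default 20).
#' @return List with `binary` (0/1 matrix, same dimnames) and `thresholds`
#'   (named vector; `NA` where no threshold was fitted).
#' @export
binarize_auc <- function(auc, min_cells = 20L) {
  vals <- if (inherits(auc, "auc_matrix")) auc$values else auc
  if (ncol(vals) < min_cells)
    stop(sprintf("need at least %d cells", min_cells))
  bin <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  thresholds <- setNames(rep(NA_real_, nrow(vals)), rownames(vals))
  for (r in seq_len(nrow(vals))) {
    x <- as.numeric(vals[r, ])
    if (stats::sd(x) < 1e-12) {
      warning(sprintf("regulon '%s' is constant; all cells set to 0",
                      rownames(vals)[r]))
      next
    }
    mc <- suppressWarnings(
      mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"), verbose = FALSE))
    if (is.null(mc) || mc$G == 1L) {
      warning(sprintf("regulon '%s' looks unimodal; all cells set to 0",
                      rownames(vals)[r]))
      next
    }
    par <- mc$parameters
    sds <- sqrt(if (length(par$variance$sigmasq) == 1L)
      rep(par$variance$sigmasq, 2L) else par$variance$sigmasq)
    thr <- .gmm_threshold(par$pro, par$mean, sds)
    thresholds[r] <- thr
    bin[r, x > thr] <- 1L
  }
  list(binary = bin, thresholds = thresholds)
}

#' Percentage of active cells per regulon and cluster
#'
#' Counts the cells with value 1 in the binarized AUC matrix and divides by
#' the cluster size, scaled to percent.
#'
#' @param binary Regulons x cells 0/1 matrix.
#' @param clusters Per-cell cluster labels.
#' @return Regulons x clusters matrix of percentages in `[0, 100]`.
#' @export
percent_active <- function(binary, clusters) {
  if (length(clusters) != ncol(binary))
    stop("one cluster label per cell required")
  if (any(is.na(clusters))) stop("every cell must have a cluster")
  clusters <- factor(clusters)
  if (any(table(clusters) == 0)) stop("empty cluster")
  lv <- levels(clusters)
  out <- matrix(0, nrow(binary), length(lv),
                dimnames = list(rownames(binary), lv))
  for (cl in lv) {
    idx <- clusters == cl
    out[, cl] <- 100 * rowSums(binary[, idx, drop = FALSE]) / sum(idx)
  }
  out
}

# Jensen-Shannon divergence (base 2) between two probability vectors.
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity score (RSS)
#'
#' For regulon R and cluster C, normalizes R's AUC values across cells to a
#' probability vector and compares it to the normalized indicator of
#' membership in C: `RSS = 1 - sqrt(JSD)` with the Jensen-Shannon
#' divergence in base 2, so RSS lies in `[0, 1]` and equals 1 when activity
#' is exactly proportional to the cluster indicator.
#'
#' @param auc Regulons x cells matrix of non-negative activity values.
#' @param clusters Per-cell cluster labels.
#' @return Regulons x clusters matrix of RSS values; rows of all-zero
#'   regulons are `NA`.
#' @export
regulon_rss <- function(auc, clusters) {
  vals <- if (inherits(auc, "auc_matrix")) auc$values else auc
  if (any(vals < 0)) stop("RSS requires non-negative AUC values")
  if (length(clusters) != ncol(vals))
    stop("one cluster label per cell required")
  clusters <- factor(clusters)
  out <- matrix(NA_real_, nrow(vals), nlevels(clusters),
                dimnames = list(rownames(vals), levels(clusters)))
  for (r in seq_len(nrow(vals))) {
    tot <- sum(vals[r, ])
    if (tot == 0) next
    p <- vals[r, ] / tot
    for (cl in levels(clusters)) {
      ind <- as.numeric(clusters == cl)
      q <- ind / sum(ind)
      # floating-point cancellation can leave a tiny negative divergence
      out[r, cl] <- 1 - sqrt(max(.jsd2(p, q), 0))
    }
  }
  out
}

#' Top-k regulons per cluster by specificity
#'
#' @param rss Regulons x clusters RSS matrix (from [regulon_rss()]).
#' @param k Number of regulons per cluster (default 5, the conventional
#'   choice). Ties are broken by regulon name; fewer regulons than `k`
#'   returns all with a warning.
#' @return Named list cluster -> ordered character vector of regulons.
#' @export
top_regulons <- function(rss, k = 5L) {
  if (k < 1) stop("k must be >= 1")
  usable <- rowSums(is.na(rss)) < ncol(rss)
  if (sum(usable) < k)
    warning(sprintf("only %d regulon(s) available for k = %d", sum(usable), k))
  out <- lapply(colnames(rss), function(cl) {
    v <- rss[, cl]
    v <- v[!is.na(v)]
    ord <- order(-v, names(v))
    names(v)[ord][seq_len(min(k, length(v)))]
  })
  names(out) <- colnames(rss)
  out
}

#' Trim a regulon network at the per-regulon third quartile of importance
#'
#' Per regulon, computes the third quartile (Q3) of its target importance
#' scores (linear-interpolation quantile, type 7) and retains targets with
#' importance strictly greater than Q3. If the strict filter empties a
#' regulon, its single maximum-importance target is kept with a warning.
#'
#' @param edges Data.frame with columns `tf`, `target`, `importance`
#'   (positive; no duplicate targets within a regulon).
#' @return Trimmed edge data.frame; attribute `quantile_type` records the
#'   quantile convention used.
#' @export
trim_network <- function(edges) {
  need <- c("tf", "target", "importance")
  if (!all(need %in% names(edges)))
    stop("edges must have tf, target, importance columns")
  if (any(edges$importance <= 0)) stop("importance values must be positive")
  if (anyDuplicated(edges[, c("tf", "target")]))
    stop("duplicate targets within a regulon")
  kept <- lapply(split(edges, edges$tf), function(e) {
    q3 <- stats::quantile(e$importance, 0.75, type = 7, names = FALSE)
    keep <- e$importance > q3
    if (!any(keep)) {
      warning(sprintf(
        "regulon '%s': strict Q3 filter empties it; keeping max-importance target",
        e$tf[1L]))
      keep <- seq_len(nrow(e)) == which.max(e$importance)
    }
    e[keep, , drop = FALSE]
  })
  out <- do.call(rbind, c(kept, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  attr(out, "quantile_type") <- 7L
  out
}
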